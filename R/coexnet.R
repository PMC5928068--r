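#' Welch t-test filter between vegetative and reproductive samples
#'
#' Two-sided Welch two-sample t-test per gene; genes with `p < alpha` are
#' retained. Abundances are tested on the `log2(x + 1)` scale by default
#' (variance-stabilising for FPKM-like values; the t-test is then calibrated
#' under multiplicative noise). No multiple-testing correction is applied
#' (the selection is a screening step for the correlation network, not an
#' inference). Degenerate genes with zero variance in both groups get
#' `p = 1` when the group means are equal and `p = 0` otherwise.
#'
#' @param m Genes x samples expression matrix.
#' @param classes Character vector over samples with exactly two levels
#'   (e.g. `"vegetative"` / `"reproductive"`), at least 2 samples each.
#' @param alpha Retention level (default 0.05).
#' @param log2_transform Test `log2(x + 1)` instead of raw values
#'   (default `TRUE`).
#' @return Data frame `gene`, `t`, `p`, `retained`.
#' @export
de_filter <- function(m, classes, alpha = 0.05, log2_transform = TRUE) {
  stopifnot(is.matrix(m), length(classes) == ncol(m))
  lev <- unique(classes)
  if (length(lev) != 2L) stop("classes must have exactly two levels")
  if (any(table(classes) < 2L)) stop("each class needs at least 2 samples")
  if (log2_transform) {
    if (any(m < 0)) stop("negative values under log2_transform")
    m <- log2(m + 1)
  }
  g1 <- classes == lev[1L]
  g2 <- classes == lev[2L]
  tt <- vapply(seq_len(nrow(m)), function(i) {
    x <- m[i, g1]; y <- m[i, g2]
    if (sd(x) == 0 && sd(y) == 0) {
      if (mean(x) == mean(y)) return(c(0, 1))
      return(c(sign(mean(x) - mean(y)) * Inf, 0))
    }
    r <- t.test(x, y, var.equal = FALSE)
    c(unname(r$statistic), r$p.value)
  }, numeric(2))
  data.frame(gene = rownames(m), t = tt[1L, ], p = tt[2L, ],
             retained = tt[2L, ] < alpha,
             stringsAsFactors = FALSE)
}

#' Pearson correlation matrix across samples
#'
#' @param m Genes x samples matrix (>= 2 genes, >= 3 samples). Constant
#'   genes are excluded with a warning.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pcc_matrix <- function(m) {
  stopifnot(is.matrix(m))
  if (ncol(m) < 3L) stop("need at least 3 samples")
  v <- apply(m, 1L, sd)
  if (any(v == 0)) {
    warning("excluding constant genes: ",
            paste(rownames(m)[v == 0], collapse = ", "))
    m <- m[v > 0, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("need at least 2 non-constant genes")
  cor(t(m))
}

#' Train the correlation threshold that minimises network density
#'
#' For each threshold on the grid a graph is built with the edge rule
#' `r >= tau` (or `|r| >= tau` with `rule = "absolute"`); its density is
#' `2E / (Nc (Nc - 1))` over the `Nc` non-isolated nodes (0 when `Nc < 2`).
#' The trained threshold is the grid value minimising density, ties resolved
#' towards the largest threshold (the sparsest graph).
#'
#' @param r Correlation matrix (as from [pcc_matrix()]).
#' @param grid Candidate thresholds (default 0.50 to 0.99 by 0.01).
#' @param rule `"signed"` (default; co-expression only) or `"absolute"`.
#' @return List with `tau` (trained threshold), `profile` (data frame `tau`,
#'   `n_edges`, `n_nodes`, `density`) and `empty` (`TRUE` when no threshold
#'   yields any edge, in which case `tau` is the largest grid value).
#' @export
train_threshold <- function(r, grid = seq(0.50, 0.99, by = 0.01),
                            rule = c("signed", "absolute")) {
  rule <- match.arg(rule)
  if (length(grid) == 0L) stop("empty threshold grid")
  grid <- sort(grid)
  ut <- upper.tri(r)
  ij <- which(ut, arr.ind = TRUE)
  w <- r[ut]
  if (rule == "absolute") w <- abs(w)
  prof <- data.frame(tau = grid, n_edges = NA_integer_,
                     n_nodes = NA_integer_, density = NA_real_)
  for (k in seq_along(grid)) {
    sel <- w >= grid[k]
    e <- sum(sel)
    nc <- length(unique(c(ij[sel, 1L], ij[sel, 2L])))
    prof$n_edges[k] <- e
    prof$n_nodes[k] <- nc
    prof$density[k] <- if (nc < 2L) 0 else 2 * e / (nc * (nc - 1))
  }
  if (all(prof$n_edges == 0L)) {
    return(list(tau = max(grid), profile = prof, empty = TRUE))
  }
  best <- max(which(prof$density == min(prof$density)))
  list(tau = grid[best], profile = prof, empty = FALSE)
}

#' Build the thresholded correlation graph
#'
#' @param r Correlation matrix.
#' @param tau Threshold in `(0, 1]`.
#' @param rule `"signed"` (edge when `r >= tau`) or `"absolute"`
#'   (`|r| >= tau`).
#' @return An undirected [igraph] graph over all genes (isolated nodes kept),
#'   edge attribute `weight` = r, graph attributes `tau` and `density`
#'   (over non-isolated nodes).
#' @export
build_graph <- function(r, tau, rule = c("signed", "absolute")) {
  rule <- match.arg(rule)
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  w <- if (rule == "absolute") abs(r) else r
  adj <- w >= tau
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ends <- igraph::as_edgelist(g)
  igraph::E(g)$weight <- r[cbind(ends[, 1L], ends[, 2L])]
  deg <- igraph::degree(g)
  nc <- sum(deg > 0)
  g <- igraph::set_graph_attr(g, "tau", tau)
  igraph::set_graph_attr(g, "density",
                         if (nc < 2) 0 else
                           2 * igraph::ecount(g) / (nc * (nc - 1)))
}

#' Extract family-anchored modules from a correlation graph
#'
#' The extracted subgraph keeps the family nodes, their direct neighbours,
#' and only the edges incident to at least one family node; modules are the
#' connected components of this subgraph. Per module the family members,
#' adjacent genes, edge count, per-family-gene degree and the counts of
#' adjacent genes with at least k family connections (k = 2, 4, 5) are
#' reported.
#'
#' @param g Graph from [build_graph()].
#' @param family_ids Family gene ids; ids absent from the graph are reported
#'   and skipped. Family genes without edges form singleton modules.
#' @return List of `module_summary` lists: `module_id`, `family_ids`,
#'   `adjacent_ids`, `n_edges`, `family_degree`, `tallies` (named counts for
#'   `k2`, `k4`, `k5`).
#' @export
extract_family_modules <- function(g, family_ids) {
  if (length(family_ids) == 0L) stop("empty family set")
  missing <- setdiff(family_ids, igraph::V(g)$name)
  if (length(missing) > 0L) {
    warning("family ids absent from graph, skipped: ",
            paste(missing, collapse = ", "))
  }
  fam <- intersect(family_ids, igraph::V(g)$name)
  if (length(fam) == 0L) stop("no family gene present in the graph")
  ends <- igraph::as_edgelist(g)
  fam_incident <- ends[, 1L] %in% fam | ends[, 2L] %in% fam
  eidx <- which(fam_incident)
  keep_nodes <- unique(c(fam, ends[fam_incident, 1L], ends[fam_incident, 2L]))
  sub <- igraph::subgraph_from_edges(g, eidx, delete.vertices = TRUE)
  iso <- setdiff(keep_nodes, igraph::V(sub)$name)
  if (length(iso) > 0L) sub <- igraph::add_vertices(sub, length(iso), name = iso)
  comp <- igraph::components(sub)
  out <- list()
  for (ci in seq_len(comp$no)) {
    nodes <- igraph::V(sub)$name[comp$membership == ci]
    fam_in <- intersect(nodes, fam)
    adj_in <- setdiff(nodes, fam)
    sg <- igraph::induced_subgraph(sub, nodes)
    deg <- igraph::degree(sg)
    deg <- setNames(as.integer(deg), names(deg))
    out[[ci]] <- structure(list(
      module_id = sprintf("module%d", ci),
      family_ids = sort(fam_in),
      adjacent_ids = sort(adj_in),
      n_edges = as.integer(igraph::ecount(sg)),
      family_degree = deg[sort(fam_in)],
      tallies = c(k2 = sum(deg[adj_in] >= 2),
                  k4 = sum(deg[adj_in] >= 4),
                  k5 = sum(deg[adj_in] >= 5))
    ), class = "module_summary")
  }
  # largest modules first, ties by first family id
  ord <- order(-vapply(out, function(m)
    length(m$family_ids) + length(m$adjacent_ids), 1L),
    vapply(out, function(m) m$family_ids[1L] %||% "", ""))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$module_id <- sprintf("module%d", i)
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Count adjacent genes with at least k family connections
#'
#' @param ms A `module_summary` from [extract_family_modules()].
#' @param k Minimum number of family-gene edges (>= 1).
#' @return List `count` and `percentage` (of the module's adjacent genes,
#'   one decimal).
#' @export
connectivity_tally <- function(ms, k) {
  stopifnot(inherits(ms, "module_summary"), k >= 1)
  n_adj <- length(ms$adjacent_ids)
  if (n_adj == 0L) return(list(count = 0L, percentage = 0))
  # adjacent-node degree within the extracted subgraph equals its number of
  # family connections (only family-incident edges are retained)
  deg <- attr(ms, "adjacent_degree")
  cnt <- if (!is.null(deg)) sum(deg >= k) else
    switch(as.character(k),
           "1" = n_adj,
           unname(ms$tallies[paste0("k", k)]))
  if (is.na(cnt)) stop("tally for k = ", k, " not available in the summary")
  list(count = as.integer(cnt),
       percentage = round(100 * cnt / n_adj, 1))
}

#' Construct a module summary from explicit per-gene family connections
#'
#' Useful for tallying published module figures: supply the number of family
#' connections of every adjacent gene.
#'
#' @param family_ids Family gene ids.
#' @param adjacent_connections Named (or unnamed) integer vector: family
#'   connections per adjacent gene (each >= 1).
#' @return A `module_summary`.
#' @export
module_summary_from_counts <- function(family_ids, adjacent_connections) {
  stopifnot(all(adjacent_connections >= 1L))
  ids <- names(adjacent_connections)
  if (is.null(ids)) {
    ids <- sprintf("adj%04d", seq_along(adjacent_connections))
    names(adjacent_connections) <- ids
  }
  ms <- structure(list(
    module_id = "module1",
    family_ids = sort(family_ids),
    adjacent_ids = sort(ids),
    n_edges = sum(adjacent_connections),
    family_degree = NULL,
    tallies = c(k2 = sum(adjacent_connections >= 2),
                k4 = sum(adjacent_connections >= 4),
                k5 = sum(adjacent_connections >= 5))
  ), class = "module_summary")
  attr(ms, "adjacent_degree") <- adjacent_connections
  ms
}

#' Tissue-specificity calls
#'
#' A gene is vegetative-specific when it reaches `epsilon` in at least one
#' vegetative sample and stays below `epsilon` in every reproductive sample;
#' the reproductive-specific definition is symmetric; everything else is
#' `"none"`.
#'
#' @param m Genes x samples matrix.
#' @param genes Genes to call; absent genes are reported and skipped.
#' @param classes Sample classes (`"vegetative"` / `"reproductive"`).
#' @param epsilon Detection threshold (>= 0, default 1).
#' @return Data frame `gene`, `class`.
#' @export
tissue_specific <- function(m, genes, classes, epsilon = 1) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  stopifnot(length(classes) == ncol(m))
  absent <- setdiff(genes, rownames(m))
  if (length(absent) > 0L) {
    warning("genes absent from matrix, skipped: ",
            paste(absent, collapse = ", "))
    genes <- setdiff(genes, absent)
  }
  veg <- classes == "vegetative"
  rep_ <- classes == "reproductive"
  cls <- vapply(genes, function(g) {
    x <- m[g, ]
    if (any(x[veg] >= epsilon) && all(x[rep_] < epsilon)) return("vegetative-specific")
    if (any(x[rep_] >= epsilon) && all(x[veg] < epsilon)) return("reproductive-specific")
    "none"
  }, character(1))
  data.frame(gene = genes, class = unname(cls), stringsAsFactors = FALSE)
}

#' Hypergeometric term enrichment with Benjamini-Hochberg correction
#'
#' For each term with at least one annotated background gene, the upper-tail
#' hypergeometric probability `P(X >= k)` of seeing `k` annotated genes in a
#' sample of `n` from a background of `M` genes of which `K` carry the term;
#' q-values are BH-adjusted across all tested terms.
#'
#' @param sample_genes Genes of interest (must be a subset of `background`).
#' @param map Annotation data frame with columns `gene`, `term`.
#' @param background Background gene universe.
#' @return Data frame `term`, `k`, `n`, `K`, `M`, `p`, `q`, sorted by `q`
#'   then `p`.
#' @export
hypergeom_enrichment <- function(sample_genes, map, background) {
  if (!all(sample_genes %in% background)) {
    stop("sample genes must be a subset of the background")
  }
  map <- map[map$gene %in% background, , drop = FALSE]
  terms <- sort(unique(map$term))
  M <- length(unique(background))
  n <- length(unique(sample_genes))
  rows <- lapply(terms, function(tm) {
    tg <- unique(map$gene[map$term == tm])
    K <- length(tg)
    if (K == 0L) return(NULL)
    k <- length(intersect(tg, sample_genes))
    p <- phyper(k - 1L, K, M - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, M = M, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), M = integer(0), p = numeric(0),
                      q = numeric(0)))
  }
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$q, out$p, out$term), , drop = FALSE]
}
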