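#' Pairwise p-distance between two aligned protein blocks
#'
#' Positions where either sequence carries `X` (unknown residue) are excluded
#' from both the difference and the comparison count.
#'
#' @param a,b Equal-length protein strings.
#' @return Fraction of differing positions among compared positions.
#' @export
p_distance <- function(a, b) {
  ca <- .chars(a); cb <- .chars(b)
  if (length(ca) != length(cb)) stop("blocks must have equal length")
  ok <- ca != "X" & cb != "X"
  if (!any(ok)) stop("all positions excluded for pair")
  mean(ca[ok] != cb[ok])
}

#' p-distance matrix over a set of aligned blocks
#'
#' @param blocks Named character vector of equal-length protein blocks
#'   (two or more).
#' @return Symmetric matrix of p-distances with zero diagonal.
#' @export
p_distance_matrix <- function(blocks) {
  if (length(blocks) < 2L) stop("need at least 2 blocks")
  L <- unique(nchar(blocks))
  if (length(L) != 1L) stop("blocks must have equal length")
  ids <- names(blocks)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(blocks))
  n <- length(blocks)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  ch <- do.call(rbind, lapply(blocks, .chars))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- ch[i, ] != "X" & ch[j, ] != "X"
      if (!any(ok)) stop("all positions excluded for pair ",
                         ids[i], " / ", ids[j])
      m[i, j] <- m[j, i] <- mean(ch[i, ok] != ch[j, ok])
    }
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining: at each step the pair minimising the
#' Q-criterion is joined; ties are broken by the lexicographically smallest
#' pair of node labels (an internal node carries the smaller of its
#' children's labels for this purpose). Negative branch lengths are clamped
#' to zero.
#'
#' @param d Symmetric distance matrix with row/column names and zero
#'   diagonal; at least 3 taxa.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  labs <- rownames(d)
  if (is.null(labs)) stop("distance matrix must have row names")
  frag <- labs
  D <- d
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (length(labs) > 3L) {
    m <- length(labs)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- apply(cand, 1L, function(rc) {
      p <- sort(c(labs[rc[1L]], labs[rc[2L]]))
      paste(p, collapse = "\r")
    })
    sel <- cand[order(key)[1L], ]
    i <- sel[[1L]]; j <- sel[[2L]]
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(bi), frag[j], fmt(bj))
    newlab <- min(labs[c(i, j)])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    labs <- c(labs[keep], newlab)
    frag <- c(frag[keep], newfrag)
    dimnames(D) <- list(labs, labs)
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(b1), frag[2], fmt(b2), frag[3], fmt(b3))
  ape::read.tree(text = nwk)
}

# distances from one query block to every panel entry
.panel_distances <- function(query, panel) {
  vapply(panel$block, function(b) p_distance(query, b), numeric(1),
         USE.NAMES = FALSE)
}

#' Assign a query block to a clade by nearest-reference voting
#'
#' The label is the majority among the `m` nearest references by p-distance;
#' a label tie is broken by the smallest nearest distance among the tied
#' labels, then by the label of the single nearest reference.
#'
#' @param query Protein block of the panel's block length.
#' @param panel Reference panel data frame with columns `id`, `species`,
#'   `clade`, `block` (as from [gen_reference_panel()]).
#' @param m Number of nearest neighbours to vote (default 3).
#' @return One-row data frame: `label`, `support` (vote fraction),
#'   `nearest_id`, `nearest_dist`.
#' @export
assign_clade <- function(query, panel, m = 3L) {
  if (nrow(panel) == 0L) stop("empty reference panel")
  if (m < 1L) stop("m must be >= 1")
  L <- unique(nchar(panel$block))
  if (length(L) != 1L) stop("panel blocks must have equal length")
  if (nchar(query) != L) stop("query length differs from panel block length")
  dist <- .panel_distances(query, panel)
  ord <- order(dist, panel$id)
  m <- min(m, nrow(panel))
  top <- ord[seq_len(m)]
  votes <- table(panel$clade[top])
  winners <- names(votes)[votes == max(votes)]
  if (length(winners) > 1L) {
    nearest_by_label <- vapply(winners, function(lb)
      min(dist[top][panel$clade[top] == lb]), numeric(1))
    winners <- winners[nearest_by_label == min(nearest_by_label)]
    if (length(winners) > 1L) winners <- panel$clade[ord[1L]]
  }
  data.frame(label = winners[1L],
             support = as.numeric(max(votes)) / m,
             nearest_id = panel$id[ord[1L]],
             nearest_dist = dist[ord[1L]],
             stringsAsFactors = FALSE)
}

#' Classify a set of query blocks against a reference panel
#'
#' Adds the family-membership decision: a query is accepted as a family
#' (MIKC-type) member when its label is not the outgroup label and its
#' nearest reference distance does not exceed `d_accept`.
#'
#' @param queries Named character vector of query blocks.
#' @inheritParams assign_clade
#' @param d_accept Maximum nearest-reference distance for acceptance
#'   (default 0.4).
#' @param outgroup_label Panel label treated as non-family.
#' @return Data frame with one row per query: `query_id`, `label`, `support`,
#'   `nearest_id`, `nearest_dist`, `accepted`.
#' @export
classify_blocks <- function(queries, panel, m = 3L, d_accept = 0.4,
                            outgroup_label = "MIKC*-outgroup") {
  rows <- lapply(names(queries), function(id) {
    a <- assign_clade(queries[[id]], panel, m = m)
    cbind(data.frame(query_id = id, stringsAsFactors = FALSE), a)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$accepted <- out$label != outgroup_label & out$nearest_dist <= d_accept
  out
}

#' Detect closely related paralogous pairs within one species
#'
#' Pairs (i, j) such that j is i's nearest same-species neighbour and vice
#' versa (nearest-neighbour ties broken by id order), with p-distance at most
#' `d_max`.
#'
#' @param blocks Named character vector of equal-length blocks (>= 2).
#' @param d_max Maximum p-distance for a pair (default 0.15).
#' @return Data frame `id1`, `id2`, `dist` with `id1 < id2`.
#' @export
find_paralog_pairs <- function(blocks, d_max = 0.15) {
  if (length(blocks) < 2L) stop("need at least 2 blocks")
  d <- p_distance_matrix(blocks)
  ids <- rownames(d)
  nn <- vapply(seq_along(ids), function(i) {
    di <- d[i, ]; di[i] <- Inf
    ids[order(di, ids)[1L]]
  }, character(1))
  names(nn) <- ids
  rows <- list()
  for (i in seq_along(ids)) {
    a <- ids[i]; b <- nn[a]
    if (nn[b] == a && a < b && d[a, b] <= d_max) {
      rows[[a]] <- data.frame(id1 = a, id2 = b, dist = d[a, b],
                              stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(id1 = character(0), id2 = character(0),
                      dist = numeric(0)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Reciprocal best hits between two sets of blocks
#'
#' Similarity score is the negative p-distance; a pair is kept when the best
#' hit is mutual (best-hit ties broken by id order).
#'
#' @param set_a,set_b Named character vectors of equal-length blocks.
#' @return Data frame `query_id`, `subject_id`, `score`, `reciprocal`.
#' @export
reciprocal_best_hits <- function(set_a, set_b) {
  if (length(set_a) == 0L || length(set_b) == 0L) stop("empty block set")
  ids_a <- names(set_a); ids_b <- names(set_b)
  d <- matrix(0, length(set_a), length(set_b), dimnames = list(ids_a, ids_b))
  for (i in seq_along(set_a)) {
    for (j in seq_along(set_b)) d[i, j] <- p_distance(set_a[[i]], set_b[[j]])
  }
  best_ab <- vapply(ids_a, function(a)
    ids_b[order(d[a, ], ids_b)[1L]], character(1))
  best_ba <- vapply(ids_b, function(b)
    ids_a[order(d[, b], ids_a)[1L]], character(1))
  keep <- ids_a[best_ba[best_ab[ids_a]] == ids_a]
  data.frame(query_id = keep,
             subject_id = unname(best_ab[keep]),
             score = -d[cbind(keep, best_ab[keep])],
             reciprocal = TRUE,
             stringsAsFactors = FALSE,
             row.names = NULL)
}
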