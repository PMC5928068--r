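#' Construct a Ct table
#'
#' @param ct Genes x samples matrix of Ct values (cycles).
#' @param ref_ids Reference gene ids (rows of `ct`); default expectation is
#'   three stable references.
#' @param samples Optional sample annotation data frame with columns `sample`
#'   and any of `class`, `stage` (row order = columns of `ct`).
#' @param detected Logical matrix, same shape as `ct`; `FALSE` marks
#'   not-detected reactions (never encoded as 0).
#' @return A `ct_table` list: `ct`, `ref_ids`, `samples`, `detected`.
#' @export
new_ct_table <- function(ct, ref_ids, samples = NULL, detected = NULL) {
  stopifnot(is.matrix(ct), !is.null(rownames(ct)), !is.null(colnames(ct)))
  if (!all(ref_ids %in% rownames(ct))) stop("reference genes missing from table")
  if (is.null(detected)) {
    detected <- matrix(TRUE, nrow(ct), ncol(ct), dimnames = dimnames(ct))
  }
  stopifnot(identical(dim(detected), dim(ct)))
  if (any(ct[detected] <= 0)) stop("detected Ct values must be positive")
  ref_det <- detected[ref_ids, , drop = FALSE]
  if (!all(ref_det)) {
    bad <- colnames(ct)[colSums(!ref_det) > 0][1L]
    stop("reference gene not detected in sample ", bad)
  }
  if (is.null(samples)) {
    samples <- data.frame(sample = colnames(ct), stringsAsFactors = FALSE)
  }
  structure(list(ct = ct, ref_ids = ref_ids, samples = samples,
                 detected = detected),
            class = "ct_table")
}

#' Read/write Ct tables as TSV (genes in rows, samples in columns)
#'
#' Not-detected reactions are serialised as `NA`.
#'
#' @param x A `ct_table`.
#' @param path File path.
#' @param ref_ids Reference ids (needed when reading).
#' @name ct_table_io
#' @export
write_ct_table <- function(x, path) {
  m <- x$ct
  m[!x$detected] <- NA
  write_matrix_tsv(m, path)
}

#' @rdname ct_table_io
#' @export
read_ct_table <- function(path, ref_ids) {
  m <- read_matrix_tsv(path)
  det <- !is.na(m)
  m[!det] <- 99  # placeholder; masked entries are never used
  new_ct_table(m, ref_ids, detected = det)
}

#' Relative expression by the 2^-dCt method
#'
#' Per sample, `dCt = Ct_gene - mean(Ct of the reference genes)` and the
#' relative expression is `2^-dCt`. The not-detected mask is propagated
#' (`NA`), never coerced to zero.
#'
#' @param x A `ct_table` (references must be detected in every sample).
#' @return A `rel_expr` list: `values` (genes x samples, positive, `NA` where
#'   masked), `detected`, `samples`.
#' @export
relative_expression <- function(x) {
  stopifnot(inherits(x, "ct_table"))
  ref_mean <- colMeans(x$ct[x$ref_ids, , drop = FALSE])
  values <- 2^(-sweep(x$ct, 2L, ref_mean))
  values[!x$detected] <- NA_real_
  structure(list(values = values, detected = x$detected,
                 samples = x$samples),
            class = "rel_expr")
}

#' Stage-wise signed fold changes
#'
#' Replicate samples of a stage are averaged (over detected replicates)
#' first; each stage is then compared with the previous stage in `stage_order`
#' as the ratio `r = stage_s / stage_(s-1)`, reported as `r` when `r >= 1`
#' and `-1/r` otherwise (so `|FC| >= 1` with the sign giving the direction).
#' Transitions whose previous stage is undetected or zero are `NA` and
#' flagged.
#'
#' @param re A `rel_expr` from [relative_expression()] (its `samples` must
#'   carry a `stage` column), or a plain genes x samples matrix with
#'   `stages` supplied.
#' @param stage_order Ordered character vector of stages (>= 2).
#' @param stages Stage per sample when `re` is a plain matrix.
#' @return List with `fc` (genes x transitions matrix) and `undefined`
#'   (logical matrix flagging transitions without a defined value).
#' @export
stage_fold_change <- function(re, stage_order, stages = NULL) {
  if (inherits(re, "rel_expr")) {
    values <- re$values
    stages <- re$samples$stage
  } else {
    values <- re
  }
  if (is.null(stages)) stop("stage annotation required")
  if (length(stage_order) < 2L) stop("need at least 2 ordered stages")
  if (!all(stage_order %in% stages)) stop("stage_order has stages with no samples")
  stage_means <- matrix(
    vapply(stage_order, function(s) {
      rowMeans(values[, stages == s, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(values))),
    nrow = nrow(values), dimnames = list(rownames(values), stage_order))
  stage_means[is.nan(stage_means)] <- NA_real_  # all replicates masked
  trans <- sprintf("%s->%s", stage_order[-length(stage_order)],
                   stage_order[-1L])
  fc <- matrix(NA_real_, nrow(values), length(trans),
               dimnames = list(rownames(values), trans))
  undef <- matrix(FALSE, nrow(values), length(trans),
                  dimnames = dimnames(fc))
  for (s in seq_along(trans)) {
    prev <- stage_means[, s]
    cur <- stage_means[, s + 1L]
    bad <- is.na(prev) | prev == 0 | is.na(cur)
    r <- cur / prev
    fc[, s] <- ifelse(bad, NA_real_, ifelse(r >= 1, r, -1 / r))
    undef[, s] <- bad
  }
  list(fc = fc, undefined = undef)
}

#' Hierarchical clustering with Pearson correlation distance
#'
#' Distance `1 - r` (range 0..2), average linkage, cut to `K` clusters.
#' Constant-profile genes are excluded with a warning; genes are sorted by id
#' before clustering so the result is invariant to input order.
#'
#' @param m Genes x conditions matrix.
#' @param K Number of clusters.
#' @return List with `assignment` (named integer vector over usable genes),
#'   `tree` (the [stats::hclust] merge tree) and `excluded` (constant genes).
#' @export
correlation_cluster <- function(m, K) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  m <- m[order(rownames(m)), , drop = FALSE]
  v <- apply(m, 1L, sd)
  excluded <- rownames(m)[v == 0 | is.na(v)]
  if (length(excluded) > 0L) {
    warning("excluding constant-profile genes: ",
            paste(excluded, collapse = ", "))
    m <- m[!(rownames(m) %in% excluded), , drop = FALSE]
  }
  if (K > nrow(m)) stop("K exceeds the number of usable genes")
  d <- as.dist(1 - cor(t(m)))
  tree <- hclust(d, method = "average")
  assignment <- cutree(tree, k = K)
  list(assignment = assignment, tree = tree, excluded = excluded)
}

#' Detection summary per clade
#'
#' A gene is detected when its maximum value reaches `epsilon`; a clade is
#' detected when at least one member gene is. Percentages are reported to one
#' decimal.
#'
#' @param m Genes x samples matrix.
#' @param gene_clades Named character vector mapping gene id to clade label.
#' @param epsilon Detection threshold (>= 0, default 1 in FPKM-like units).
#' @param clades Universe of valid clade labels (default
#'   [mikc_clades()] without outgroup); unknown labels are rejected.
#' @return List with `genes` (per-gene detection), `clades` (per-clade counts
#'   and percentage of members detected), `n_clades_detected`,
#'   `pct_clades_detected`.
#' @export
detection_summary <- function(m, gene_clades, epsilon = 1,
                              clades = mikc_clades(outgroup = FALSE)) {
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (!all(gene_clades %in% clades)) {
    stop("unknown clade label: ",
         paste(setdiff(gene_clades, clades), collapse = ", "))
  }
  genes <- intersect(names(gene_clades), rownames(m))
  if (length(genes) == 0L) stop("no annotated gene found in the matrix")
  det <- apply(m[genes, , drop = FALSE], 1L, max, na.rm = TRUE) >= epsilon
  per_clade <- do.call(rbind, lapply(clades, function(cl) {
    mem <- genes[gene_clades[genes] == cl]
    nd <- sum(det[mem])
    data.frame(clade = cl, n_genes = length(mem), n_detected = nd,
               pct_detected = if (length(mem) > 0)
                 round(100 * nd / length(mem), 1) else NA_real_,
               detected = nd > 0L, stringsAsFactors = FALSE)
  }))
  ncl <- nrow(per_clade)
  ndet <- sum(per_clade$detected)
  list(genes = det, clades = per_clade,
       n_clades_detected = ndet,
       pct_clades_detected = round(100 * ndet / ncl, 1))
}
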