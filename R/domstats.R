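#' Per-site divergence of an aligned block set
#'
#' For each column the divergence rate is the fraction of differing unordered
#' sequence pairs among all comparable pairs; positions carrying `X` are
#' excluded pairwise. A per-column residue frequency table (over comparable
#' residues) is returned alongside.
#'
#' @param blocks Named character vector of equal-length protein blocks
#'   (two or more).
#' @return List with `rates` (length-L numeric, `NA` where fewer than two
#'   comparable residues) and `freq` (L x 20 matrix of residue frequencies).
#' @export
site_divergence <- function(blocks) {
  if (length(blocks) < 2L) stop("need at least 2 entries")
  L <- unique(nchar(blocks))
  if (length(L) != 1L) stop("blocks must have equal length")
  ch <- do.call(rbind, lapply(blocks, .chars))
  rates <- numeric(L)
  freq <- matrix(0, L, 20L, dimnames = list(NULL, AA20))
  for (j in seq_len(L)) {
    v <- ch[, j]
    v <- v[v %in% AA20]
    k <- length(v)
    if (k >= 1L) {
      freq[j, ] <- as.numeric(table(factor(v, levels = AA20))) / k
    }
    if (k < 2L) {
      rates[j] <- NA_real_
      next
    }
    tot <- choose(k, 2L)
    same <- sum(choose(table(v), 2L))
    rates[j] <- (tot - same) / tot
  }
  list(rates = rates, freq = freq)
}

#' Lineage-specific residues in an aligned block set
#'
#' A column is flagged with residue `r` when every focal-group entry carries
#' `r` there and no other-group entry does. Column numbering is 1-based from
#' the first profile column.
#'
#' @param blocks Named character vector of equal-length protein blocks.
#' @param groups Character vector (same length/order) with values `"focal"`
#'   or `"other"`; both groups must be non-empty.
#' @return Data frame `site`, `residue` (zero rows when nothing is flagged).
#' @export
lineage_specific_sites <- function(blocks, groups) {
  stopifnot(length(blocks) == length(groups))
  if (!any(groups == "focal") || !any(groups == "other")) {
    stop("both species groups must be non-empty")
  }
  L <- unique(nchar(blocks))
  if (length(L) != 1L) stop("blocks must have equal length")
  ch <- do.call(rbind, lapply(blocks, .chars))
  foc <- ch[groups == "focal", , drop = FALSE]
  oth <- ch[groups == "other", , drop = FALSE]
  sites <- integer(0); residues <- character(0)
  for (j in seq_len(L)) {
    u <- unique(foc[, j])
    if (length(u) == 1L && u %in% AA20 && !(u %in% oth[, j])) {
      sites <- c(sites, j)
      residues <- c(residues, u)
    }
  }
  data.frame(site = sites, residue = residues, stringsAsFactors = FALSE)
}

# ---- Nei-Gojobori (1986) Ka/Ks -------------------------------------------

# per-codon synonymous change counts (numerator out of 3 per position);
# changes creating a stop codon count as nonsynonymous so that S + N = 3
# holds exactly per codon site
.ng86_tables_cache <- new.env(parent = emptyenv())
.ng86_syn_changes <- function(code = Biostrings::GENETIC_CODE) {
  key <- paste(code, collapse = "")
  hit <- .ng86_tables_cache[[key]]
  if (!is.null(hit)) return(hit)
  codons <- names(code)
  syn <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (code[[cd]] == "*") { syn[cd] <- NA_real_; next }
    nts <- .chars(cd)
    cnt <- 0L
    for (p in 1:3) {
      for (b in setdiff(DNA4, nts[p])) {
        alt <- nts; alt[p] <- b
        altc <- paste(alt, collapse = "")
        if (code[[altc]] == code[[cd]]) cnt <- cnt + 1L
      }
    }
    syn[cd] <- cnt
  }
  .ng86_tables_cache[[key]] <- syn
  syn
}

.perms <- list(
  `1` = matrix(1L, 1, 1),
  `2` = rbind(c(1L, 2L), c(2L, 1L)),
  `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
              c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# synonymous/nonsynonymous difference counts for one codon pair, averaged
# over mutational pathways; pathways traversing stop codons are excluded
# (all-blocked pairs fall back to averaging over every pathway)
.ng86_pair_diffs <- function(c1, c2, code = Biostrings::GENETIC_CODE) {
  a <- .chars(c1); b <- .chars(c2)
  pos <- which(a != b)
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- .perms[[as.character(nd)]]
  res <- matrix(0, nrow(perms), 2L)
  valid <- logical(nrow(perms))
  for (k in seq_len(nrow(perms))) {
    cur <- a
    sdk <- 0; ndk <- 0; ok <- TRUE
    for (p in pos[perms[k, ]]) {
      nxt <- cur; nxt[p] <- b[p]
      aa_cur <- code[[paste(cur, collapse = "")]]
      aa_nxt <- code[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*" || aa_cur == "*") ok <- FALSE
      if (aa_cur == aa_nxt) sdk <- sdk + 1 else ndk <- ndk + 1
      cur <- nxt
    }
    res[k, ] <- c(sdk, ndk)
    valid[k] <- ok
  }
  use <- if (any(valid)) valid else rep(TRUE, nrow(perms))
  c(sd = mean(res[use, 1L]), nd = mean(res[use, 2L]))
}

.jc_correct <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) Ka/Ks for a pair of codon blocks
#'
#' Synonymous site counts are the average over the two sequences of per-codon
#' synonymous mutation fractions (changes producing stop codons count as
#' nonsynonymous, so `S + N = 3 * codons` exactly). Differences in
#' multi-substitution codons are averaged over all mutational pathways that
#' avoid stop codons. Proportions are Jukes-Cantor corrected,
#' `d = -(3/4) log(1 - 4p/3)`.
#'
#' @param codons_a,codons_b Equal-length nucleotide strings, a multiple of 3,
#'   with no internal stop codons.
#' @param code Genetic code table.
#' @param on_undefined `"error"` (default) to fail when a proportion reaches
#'   3/4 (correction undefined), or `"na"` to return `NA` rates instead.
#' @return A `kaks_result` list: `S`, `N`, `Sd`, `Nd`, `ps`, `pn`, `ds`
#'   (Ks), `dn` (Ka), `omega` (Ka/Ks, `NA` when Ks is 0 or undefined).
#' @export
ng86_kaks <- function(codons_a, codons_b, code = Biostrings::GENETIC_CODE,
                      on_undefined = c("error", "na")) {
  on_undefined <- match.arg(on_undefined)
  na <- nchar(codons_a)
  if (na != nchar(codons_b)) stop("codon blocks must have equal length")
  if (na %% 3L != 0L || na == 0L) stop("length must be a positive multiple of 3")
  nc <- na %/% 3L
  ca <- substring(codons_a, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
  cb <- substring(codons_b, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
  if (!all(c(ca, cb) %in% names(code))) stop("invalid codon in input")
  syn <- .ng86_syn_changes(code)
  if (anyNA(syn[ca]) || anyNA(syn[cb])) stop("stop codon in codon block")
  S <- (sum(syn[ca]) + sum(syn[cb])) / 6  # average of the two, counts / 3
  N <- 3 * nc - S
  diffs <- vapply(seq_len(nc), function(i)
    .ng86_pair_diffs(ca[i], cb[i], code), c(sd = 0, nd = 0))
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  if (on_undefined == "error" && (ps >= 0.75 || pn >= 0.75)) {
    stop("proportion of differences >= 3/4; Jukes-Cantor correction undefined")
  }
  ds <- .jc_correct(ps)
  dn <- .jc_correct(pn)
  omega <- if (is.na(ds) || is.na(dn) || ds == 0) NA_real_ else dn / ds
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 ds = ds, dn = dn, omega = omega),
            class = "kaks_result")
}

#' Mean Ka/Ks over all within-clade pairs
#'
#' Arithmetic means over pairs where the quantity is defined; pairs with an
#' undefined Jukes-Cantor correction or undefined omega (Ks = 0) are counted
#' and reported, not silently dropped.
#'
#' @param codon_blocks Named character vector of codon blocks (>= 2 entries).
#' @param code Genetic code table.
#' @return List: `mean_omega`, `mean_dn`, `mean_ds`, `n_pairs`,
#'   `n_undefined_omega`, `n_undefined_rate`, `pairs` (per-pair data frame).
#' @export
clade_mean_kaks <- function(codon_blocks, code = Biostrings::GENETIC_CODE) {
  if (length(codon_blocks) < 2L) stop("need at least 2 codon blocks")
  ids <- names(codon_blocks)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(codon_blocks))
  pr <- combn(seq_along(codon_blocks), 2L)
  rows <- lapply(seq_len(ncol(pr)), function(k) {
    i <- pr[1L, k]; j <- pr[2L, k]
    r <- ng86_kaks(codon_blocks[[i]], codon_blocks[[j]], code = code,
                   on_undefined = "na")
    data.frame(id1 = ids[i], id2 = ids[j], ds = r$ds, dn = r$dn,
               omega = r$omega, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (all(is.na(pairs$ds)) && all(is.na(pairs$dn))) {
    stop("no pair with a defined substitution rate")
  }
  list(mean_omega = if (all(is.na(pairs$omega))) NA_real_ else
         mean(pairs$omega, na.rm = TRUE),
       mean_dn = mean(pairs$dn, na.rm = TRUE),
       mean_ds = mean(pairs$ds, na.rm = TRUE),
       n_pairs = nrow(pairs),
       n_undefined_omega = sum(is.na(pairs$omega)),
       n_undefined_rate = sum(is.na(pairs$ds) | is.na(pairs$dn)),
       pairs = pairs)
}
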