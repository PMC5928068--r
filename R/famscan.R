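#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames +1..+3 translate the forward strand at offsets 0..2; frames -1..-3
#' translate the reverse complement at offsets 0..2. Trailing partial codons
#' are dropped; fuzzy codons (containing N) translate to `X`; stops are `*`.
#'
#' @param seq A nucleotide string over `A,C,G,T,N` (or a
#'   [Biostrings::DNAString]).
#' @param id Transcript identifier carried into the translations.
#' @param code Genetic code table (as [Biostrings::GENETIC_CODE]).
#' @return A list of six `frame_translation` records, each with
#'   `transcript_id`, `frame` (one of +1..+3, -1..-3), `protein` and
#'   `frame_seq` (the strand-oriented nucleotide sequence the frame reads).
#' @export
six_frame_translate <- function(seq, id = "query",
                                code = Biostrings::GENETIC_CODE) {
  .six_frame_batch(setNames(as.character(seq), id), code)[[1L]]
}

# vectorised six-frame translation of a whole (named) sequence set; returns
# one list of six frame_translation records per input sequence
.six_frame_batch <- function(seqs, code = Biostrings::GENETIC_CODE) {
  ids <- names(seqs)
  seqs <- setNames(as.character(seqs), ids)
  if (is.null(ids)) stop("sequences must be named")
  s <- Biostrings::DNAStringSet(seqs)
  n <- Biostrings::width(s)
  short <- which(n < 3L)
  for (i in short) {
    warning("sequence '", ids[i], "' shorter than one codon; ",
            "empty translations")
  }
  fwd <- seqs
  rev <- as.character(Biostrings::reverseComplement(s))
  names(rev) <- ids
  out <- lapply(seq_along(seqs), function(i) vector("list", 6L))
  k <- 0L
  for (strand in c(1L, -1L)) {
    src_chr <- if (strand == 1L) fwd else rev
    src <- Biostrings::DNAStringSet(src_chr)
    for (off in 0:2) {
      k <- k + 1L
      len <- pmax((n - off) %/% 3L, 0L)
      prot <- rep("", length(seqs))
      use <- which(len >= 1L)
      if (length(use) > 0L) {
        sub <- Biostrings::subseq(src[use], start = off + 1L,
                                  width = 3L * len[use])
        prot[use] <- as.character(Biostrings::translate(
          sub, genetic.code = code, if.fuzzy.codon = "X",
          no.init.codon = TRUE))
      }
      for (i in seq_along(seqs)) {
        out[[i]][[k]] <- structure(
          list(transcript_id = ids[i], frame = strand * (off + 1L),
               protein = prot[i], frame_seq = src_chr[[i]]),
          class = "frame_translation")
      }
    }
  }
  names(out) <- ids
  out
}

#' Build an ungapped position-specific log-odds domain profile
#'
#' `score(col, aa) = log2((count + pseudocount * bg_aa) / (n + pseudocount) /
#' bg_aa)` in bits. The default acceptance threshold is a fixed fraction of
#' the maximum attainable score (the sum of per-column maxima), calibrated so
#' that intact and moderately mutated domains pass while shuffled sequences
#' essentially never do.
#'
#' @param seed_blocks Two or more equal-length, gap-free protein strings.
#' @param background Residue background frequencies (named over the 20 amino
#'   acids, summing to 1); default uniform.
#' @param pseudocount Pseudocount weight (default 1).
#' @param bit_threshold_frac Acceptance threshold as a fraction of the maximum
#'   attainable score (default 0.6).
#' @return A `domain_profile`: list with `L`, `scores` (L x 20 matrix, bits),
#'   `background`, `pseudocount`, `bit_threshold`, `max_score`, `consensus`.
#' @export
build_profile <- function(seed_blocks,
                          background = setNames(rep(1 / 20, 20), AA20),
                          pseudocount = 1,
                          bit_threshold_frac = 0.6) {
  if (length(seed_blocks) < 2L) stop("need at least 2 seed blocks")
  L <- unique(nchar(seed_blocks))
  if (length(L) != 1L) stop("seed blocks must have equal length")
  background <- background[AA20]
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  mat <- do.call(rbind, lapply(seed_blocks, .chars))
  if (!all(mat %in% AA20)) stop("seed blocks contain gaps or non-residues")
  n <- length(seed_blocks)
  scores <- matrix(0, nrow = L, ncol = 20L, dimnames = list(NULL, AA20))
  for (j in seq_len(L)) {
    counts <- table(factor(mat[, j], levels = AA20))
    scores[j, ] <- log2((as.numeric(counts) + pseudocount * background) /
                          (n + pseudocount) / background)
  }
  max_score <- sum(apply(scores, 1L, max))
  consensus <- paste(AA20[apply(scores, 1L, which.max)], collapse = "")
  structure(list(L = L, scores = scores, background = background,
                 pseudocount = pseudocount,
                 bit_threshold = bit_threshold_frac * max_score,
                 max_score = max_score, consensus = consensus),
            class = "domain_profile")
}

# score all length-L windows of a protein; windows containing '*' or 'X'
# (any non-standard residue) are invalid
.profile_window_scores <- function(protein, profile) {
  n <- nchar(protein)
  L <- profile$L
  if (n < L) {
    return(data.frame(start = integer(0), score = numeric(0)))
  }
  idx <- match(.chars(protein), AA20)
  nw <- n - L + 1L
  sc <- numeric(nw)
  bad <- logical(nw)
  for (j in seq_len(L)) {
    v <- idx[j:(j + nw - 1L)]
    b <- is.na(v)
    bad <- bad | b
    v[b] <- 1L
    sc <- sc + profile$scores[cbind(j, v)]
  }
  data.frame(start = which(!bad), score = sc[!bad])
}

#' Scan one frame translation for domain hits
#'
#' Every stop- and X-free window of profile length is scored as the sum of
#' per-column log-odds; windows at or above the profile's `bit_threshold` are
#' returned best first (ties by smaller start). The underlying codon block is
#' recovered from the frame's strand sequence by frame arithmetic.
#'
#' @param ft A `frame_translation` from [six_frame_translate()].
#' @param profile A `domain_profile` from [build_profile()].
#' @return Data frame with `transcript_id`, `frame`, `protein_start`, `score`,
#'   `block_protein`, `block_codons` (zero rows when nothing passes).
#' @export
scan_domains <- function(ft, profile) {
  stopifnot(inherits(ft, "frame_translation"),
            inherits(profile, "domain_profile"))
  w <- .profile_window_scores(ft$protein, profile)
  w <- w[w$score >= profile$bit_threshold, , drop = FALSE]
  if (nrow(w) == 0L) {
    return(data.frame(transcript_id = character(0), frame = integer(0),
                      protein_start = integer(0), score = numeric(0),
                      block_protein = character(0),
                      block_codons = character(0)))
  }
  w <- w[order(-w$score, w$start), , drop = FALSE]
  off <- abs(ft$frame) - 1L
  nt_start <- off + 3L * (w$start - 1L) + 1L
  data.frame(
    transcript_id = ft$transcript_id,
    frame = ft$frame,
    protein_start = w$start,
    score = w$score,
    block_protein = substring(ft$protein, w$start, w$start + profile$L - 1L),
    block_codons = substring(ft$frame_seq, nt_start,
                             nt_start + 3L * profile$L - 1L),
    stringsAsFactors = FALSE
  )
}

#' Identify family members across a transcriptome
#'
#' Scans all six frames of every transcript and keeps at most one hit per
#' transcript: the best-scoring window over all frames (ties by smaller start,
#' then frame order +1, +2, +3, -1, -2, -3), matching one-domain-per-unigene
#' usage.
#'
#' @param transcripts Named [Biostrings::DNAStringSet] (or named character
#'   vector) of nucleotide unigenes.
#' @param profile A `domain_profile`.
#' @param code Genetic code table.
#' @return Data frame of best hits, one row per transcript with a hit.
#' @export
identify_family <- function(transcripts, profile,
                            code = Biostrings::GENETIC_CODE) {
  ids <- names(transcripts)
  seqs <- setNames(as.character(transcripts), ids)
  if (is.null(ids)) stop("transcripts must be named")
  frame_order <- c(1L, 2L, 3L, -1L, -2L, -3L)
  frames <- .six_frame_batch(seqs, code)
  best <- list()
  for (i in seq_along(seqs)) {
    hits <- do.call(rbind, lapply(frames[[i]],
                                  scan_domains, profile = profile))
    if (nrow(hits) == 0L) next
    hits <- hits[order(-hits$score, hits$protein_start,
                       match(hits$frame, frame_order)), , drop = FALSE]
    best[[ids[i]]] <- hits[1L, , drop = FALSE]
  }
  if (length(best) == 0L) {
    return(data.frame(transcript_id = character(0), frame = integer(0),
                      protein_start = integer(0), score = numeric(0),
                      block_protein = character(0),
                      block_codons = character(0)))
  }
  do.call(rbind, c(best, list(make.row.names = FALSE)))
}

#' Pairwise sequence identity over the shorter sequence
#'
#' Identity is the number of matched positions in the optimal local alignment
#' (match +1, mismatch -1, gap -2 per position) divided by the length of the
#' shorter sequence (the CD-HIT convention). The two inputs are put in a
#' canonical order before alignment so the result is symmetric.
#'
#' @param a,b Non-empty nucleotide strings.
#' @return Identity fraction in `[0, 1]`, with the alignment score as
#'   attribute `score`.
#' @export
pairwise_identity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  if (nchar(a) > nchar(b) || (nchar(a) == nchar(b) && a > b)) {
    tmp <- a; a <- b; b <- tmp
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "local",
    substitutionMatrix = .nt_submat(), gapOpening = 0, gapExtension = 2)
  structure(Biostrings::nmatch(aln) / min(nchar(a), nchar(b)),
            score = Biostrings::score(aln))
}

.nt_submat_cache <- new.env(parent = emptyenv())
.nt_submat <- function() {
  if (is.null(.nt_submat_cache$m)) {
    .nt_submat_cache$m <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE)
  }
  .nt_submat_cache$m
}

#' Greedy redundancy removal at an identity cutoff
#'
#' Sequences are sorted by length descending (ties by id ascending); each
#' sequence joins the first previously founded representative with identity at
#' or above `tau_id`, otherwise it founds a new cluster. Representatives form
#' the non-redundant set.
#'
#' @param records Named [Biostrings::DNAStringSet] or named character vector.
#' @param tau_id Identity threshold in `(0, 1]` (default 0.90).
#' @return A `cluster_set`: list with `clusters` (representative id ->
#'   member ids, members include the representative), `representatives`,
#'   `tau_id`.
#' @export
remove_redundancy <- function(records, tau_id = 0.90) {
  if (tau_id <= 0 || tau_id > 1) stop("tau_id must be in (0, 1]")
  ids <- names(records)
  seqs <- setNames(as.character(records), ids)
  if (is.null(ids) || anyDuplicated(ids) > 0L) {
    stop("records must have unique names")
  }
  ord <- order(-nchar(seqs), ids)
  seqs <- seqs[ord]; ids <- ids[ord]
  reps <- character(0)
  clusters <- list()
  for (i in seq_along(seqs)) {
    joined <- FALSE
    for (r in reps) {
      if (pairwise_identity(seqs[r], seqs[i]) >= tau_id) {
        clusters[[r]] <- c(clusters[[r]], ids[i])
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, ids[i])
      clusters[[ids[i]]] <- ids[i]
    }
  }
  structure(list(clusters = clusters, representatives = reps,
                 tau_id = tau_id),
            class = "cluster_set")
}
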