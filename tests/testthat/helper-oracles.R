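# Independent oracle implementations used to validate package operations.
# Each oracle is written from first principles, structurally different from
# the package code path it checks.

GC <- Biostrings::GENETIC_CODE
AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
NT <- c("A", "C", "G", "T")
SENSE_CODONS <- names(GC)[GC != "*"]

rand_dna <- function(n) paste(sample(NT, n, replace = TRUE), collapse = "")
rand_protein <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")
rand_codons <- function(n_codons) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

# brute-force codon-table translation of one frame
oracle_translate <- function(seq, offset = 0) {
  n <- nchar(seq)
  len <- (n - offset) %/% 3
  if (len < 1) return("")
  out <- character(len)
  for (i in seq_len(len)) {
    cod <- substr(seq, offset + 3 * i - 2, offset + 3 * i)
    out[i] <- if (grepl("[^ACGT]", cod)) "X" else GC[[cod]]
  }
  paste(out, collapse = "")
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# direct evaluation of the profile log-odds formula
oracle_profile_scores <- function(blocks, background, pseudocount) {
  L <- nchar(blocks[1])
  n <- length(blocks)
  ch <- do.call(rbind, strsplit(blocks, ""))
  sc <- matrix(0, L, length(AA), dimnames = list(NULL, AA))
  for (j in seq_len(L)) {
    for (a in AA) {
      cnt <- sum(ch[, j] == a)
      sc[j, a] <- log2((cnt + pseudocount * background[a]) /
                         (n + pseudocount) / background[a])
    }
  }
  sc
}

# Smith-Waterman DP (match +1 / mismatch -1 / gap -2 per position): exact
# optimal score plus the min/max number of matched positions attainable over
# all score-optimal local alignments (dual DP over co-optimal predecessors)
oracle_sw <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  Mx <- matrix(0, n + 1, m + 1)
  Mn <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      eq <- A[i] == B[j]
      s <- if (eq) match else mismatch
      diag_ <- H[i, j] + s
      up <- H[i, j + 1] + gap
      left <- H[i + 1, j] + gap
      h <- max(0, diag_, up, left)
      H[i + 1, j + 1] <- h
      mx <- -Inf; mn <- Inf
      if (h == 0) { mx <- max(mx, 0); mn <- min(mn, 0) }
      if (h == diag_) {
        mx <- max(mx, Mx[i, j] + eq); mn <- min(mn, Mn[i, j] + eq)
      }
      if (h == up) { mx <- max(mx, Mx[i, j + 1]); mn <- min(mn, Mn[i, j + 1]) }
      if (h == left) { mx <- max(mx, Mx[i + 1, j]); mn <- min(mn, Mn[i + 1, j]) }
      Mx[i + 1, j + 1] <- mx
      Mn[i + 1, j + 1] <- mn
    }
  }
  best <- max(H)
  ends <- which(H == best, arr.ind = TRUE)
  list(score = best,
       min_matches = min(Mn[ends]),
       max_matches = max(Mx[ends]))
}

# independent greedy redundancy clustering (same ordering convention,
# different code path); identity via the package's pairwise_identity
oracle_greedy_cluster <- function(seqs, tau) {
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  members <- list()
  for (id in names(seqs)) {
    placed <- NA_character_
    for (r in reps) {
      if (as.numeric(florafam::pairwise_identity(seqs[[r]], seqs[[id]])) >= tau) {
        placed <- r
        break
      }
    }
    if (is.na(placed)) {
      reps <- c(reps, id)
      members[[id]] <- id
    } else {
      members[[placed]] <- c(members[[placed]], id)
    }
  }
  list(representatives = reps, clusters = members)
}

# Nei-Gojobori 1986 from first principles: recursive pathway enumeration
oracle_ng86 <- function(s1, s2) {
  nc <- nchar(s1) / 3
  cods1 <- substring(s1, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  cods2 <- substring(s2, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  syn_sites <- function(cod) {
    nt <- strsplit(cod, "")[[1]]
    cnt <- 0
    for (p in 1:3) {
      for (bnt in setdiff(NT, nt[p])) {
        alt <- nt
        alt[p] <- bnt
        if (GC[[paste(alt, collapse = "")]] == GC[[cod]]) cnt <- cnt + 1
      }
    }
    cnt / 3
  }
  pair_diffs <- function(c1, c2) {
    if (c1 == c2) return(c(0, 0))
    a <- strsplit(c1, "")[[1]]
    b <- strsplit(c2, "")[[1]]
    acc <- list()
    recurse <- function(cur, remaining, sd, nd, blocked) {
      if (length(remaining) == 0) {
        acc[[length(acc) + 1]] <<- c(sd, nd, blocked)
        return(invisible())
      }
      for (p in remaining) {
        nxt <- cur
        nxt[p] <- b[p]
        aa1 <- GC[[paste(cur, collapse = "")]]
        aa2 <- GC[[paste(nxt, collapse = "")]]
        recurse(nxt, setdiff(remaining, p),
                sd + (aa1 == aa2), nd + (aa1 != aa2),
                blocked || aa2 == "*" || aa1 == "*")
      }
    }
    recurse(a, which(a != b), 0, 0, FALSE)
    mat <- do.call(rbind, acc)
    use <- mat[, 3] == 0
    if (!any(use)) use <- rep(TRUE, nrow(mat))
    c(mean(mat[use, 1]), mean(mat[use, 2]))
  }
  S <- (sum(vapply(cods1, syn_sites, 0)) + sum(vapply(cods2, syn_sites, 0))) / 2
  N <- 3 * nc - S
  d <- rowSums(vapply(seq_len(nc), function(i) pair_diffs(cods1[i], cods2[i]),
                      numeric(2)))
  ps <- d[1] / S
  pn <- d[2] / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = d[1], Nd = d[2], ps = ps, pn = pn,
       ds = jc(ps), dn = jc(pn))
}

# random nucleotide substitutions on a codon string, never creating a stop
mutate_codons <- function(codons, n_sub) {
  nt <- strsplit(codons, "")[[1]]
  for (k in seq_len(n_sub)) {
    repeat {
      p <- sample(length(nt), 1)
      cand <- nt
      cand[p] <- sample(setdiff(NT, nt[p]), 1)
      ci <- (p - 1) %/% 3
      cod <- paste(cand[(3 * ci + 1):(3 * ci + 3)], collapse = "")
      if (GC[[cod]] != "*") {
        nt <- cand
        break
      }
    }
  }
  paste(nt, collapse = "")
}

# closed-form Welch two-sample t-test
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# exhaustive grid scan for the density-minimising threshold
oracle_grid_scan <- function(r, grid = seq(0.50, 0.99, by = 0.01),
                             absolute = FALSE) {
  grid <- sort(grid)
  dens <- vapply(grid, function(tau) {
    w <- if (absolute) abs(r) else r
    adj <- w >= tau
    diag(adj) <- FALSE
    e <- sum(adj[upper.tri(adj)])
    nc <- sum(rowSums(adj) > 0)
    if (nc < 2) 0 else 2 * e / (nc * (nc - 1))
  }, 0)
  grid[max(which(dens == min(dens)))]
}

# exact hypergeometric upper tail by combinatorial enumeration
oracle_hyper_tail <- function(M, K, n, k) {
  xs <- k:min(n, K)
  sum(choose(K, xs) * choose(M - K, n - xs)) / choose(M, n)
}

# membership F1 of predicted vs true module gene sets
module_f1 <- function(pred, truth) {
  tp <- length(intersect(pred, truth))
  if (length(pred) + length(truth) == 0) return(1)
  2 * tp / (length(pred) + length(truth))
}
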