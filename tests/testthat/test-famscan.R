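test_that("six-frame translation handles the textbook cases", {
  fts <- six_frame_translate("ATGAAA", id = "t1")
  frames <- vapply(fts, `[[`, 0L, "frame")
  prots <- vapply(fts, `[[`, "", "protein")
  expect_identical(prots[frames == 1], "MK")
  # reverse complement of ATGAAA is TTTCAT
  expect_identical(prots[frames == -1], "FH")

  fts7 <- six_frame_translate("ATGAAAC", id = "t2")
  fwd_len <- nchar(vapply(fts7, `[[`, "", "protein")[1:3])
  expect_identical(unname(fwd_len), c(2L, 2L, 1L))
})

test_that("translation agrees with a brute-force codon lookup on all frames", {
  set.seed(41)
  for (k in 1:20) {
    s <- rand_dna(sample(10:80, 1))
    fts <- six_frame_translate(s, id = "x")
    for (ft in fts) {
      src <- if (ft$frame > 0) s else oracle_revcomp(s)
      expect_identical(ft$protein, oracle_translate(src, abs(ft$frame) - 1),
                       info = sprintf("frame %d of %s", ft$frame, s))
    }
  }
})

test_that("sequences shorter than a codon warn and translate empty", {
  expect_warning(fts <- six_frame_translate("AT", id = "tiny"), "shorter")
  expect_true(all(vapply(fts, `[[`, "", "protein") == ""))
})

test_that("profile scores follow the log-odds formula", {
  # column counts proportional to a uniform background give score 0
  blocks <- vapply(AA, function(a) paste0(a, "A"), "")
  prof <- build_profile(unname(blocks))
  expect_equal(unname(prof$scores[1, ]), rep(0, 20), tolerance = 1e-12)

  set.seed(17)
  rblocks <- vapply(1:10, function(i) rand_protein(12), "")
  prof2 <- build_profile(rblocks, pseudocount = 2)
  want <- oracle_profile_scores(rblocks,
                                setNames(rep(1 / 20, 20), AA), 2)
  expect_equal(prof2$scores, want, tolerance = 1e-12)
  # the consensus residue scores maximally in every column
  ch <- do.call(rbind, strsplit(rblocks, ""))
  for (j in seq_len(12)) {
    top <- names(which.max(table(factor(ch[, j], levels = AA))))
    expect_equal(unname(prof2$scores[j, top]), max(prof2$scores[j, ]))
  }
})

test_that("profile construction rejects bad seed blocks", {
  expect_error(build_profile("MKV"), "at least 2")
  expect_error(build_profile(c("MKV", "MK")), "equal length")
  expect_error(build_profile(c("MK-", "MKV")), "gaps")
})

test_that("scanning finds the exact consensus at the maximum score", {
  set.seed(23)
  seed_blocks <- vapply(1:8, function(i) rand_protein(20), "")
  prof <- build_profile(seed_blocks)
  target <- paste0(rand_protein(7), prof$consensus, rand_protein(5))
  ft <- structure(list(transcript_id = "q", frame = 1L, protein = target,
                       frame_seq = strrep("A", 3 * nchar(target))),
                  class = "frame_translation")
  hits <- scan_domains(ft, prof)
  expect_gte(nrow(hits), 1)
  expect_identical(hits$protein_start[1], 8L)
  expect_equal(hits$score[1], prof$max_score, tolerance = 1e-12)
})

test_that("windows containing stops are never reported", {
  set.seed(29)
  seed_blocks <- vapply(1:6, function(i) rand_protein(10), "")
  prof <- build_profile(seed_blocks)
  poisoned <- paste0(substr(prof$consensus, 1, 5), "*",
                     substr(prof$consensus, 6, 10), "*",
                     substr(prof$consensus, 1, 4))
  ft <- structure(list(transcript_id = "q", frame = 1L, protein = poisoned,
                       frame_seq = strrep("A", 3 * nchar(poisoned))),
                  class = "frame_translation")
  expect_identical(nrow(scan_domains(ft, prof)), 0L)
})

test_that("shuffled decoy translations almost never reach the threshold", {
  set.seed(31)
  panel <- gen_reference_panel(seed = 31)
  prof <- build_profile(panel$block)
  n_dec <- 2000
  hits <- 0L
  for (i in seq_len(n_dec)) {
    ft <- structure(list(transcript_id = "d", frame = 1L,
                         protein = rand_protein(prof$L),
                         frame_seq = strrep("A", 3 * prof$L)),
                    class = "frame_translation")
    if (nrow(scan_domains(ft, prof)) > 0) hits <- hits + 1L
  }
  expect_lte(hits / n_dec, 0.01)
})

test_that("domain hit codons translate back to the hit protein", {
  cfg <- synthetic_config(seed = 13,
                          domain_plant = list(n_positives = 10, n_decoys = 5,
                                              per_site_mutation_rate = 0.05))
  tr <- gen_transcriptome(cfg)
  panel <- gen_reference_panel(seed = 13)
  prof <- build_profile(panel$block)
  hits <- identify_family(tr$transcripts, prof)
  expect_gte(nrow(hits), 1)
  for (i in seq_len(nrow(hits))) {
    expect_identical(
      as.character(Biostrings::translate(
        Biostrings::DNAString(hits$block_codons[i]))),
      hits$block_protein[i])
  }
})

test_that("pairwise identity matches the hand cases and is symmetric", {
  expect_equal(as.numeric(pairwise_identity("ACGTACGT", "ACGTACGT")), 1.0)
  expect_equal(as.numeric(pairwise_identity("ACGT", "ACGA")), 0.75)
  expect_error(pairwise_identity("", "ACGT"), "empty")
  set.seed(37)
  for (k in 1:10) {
    a <- rand_dna(60); b <- rand_dna(45)
    expect_identical(as.numeric(pairwise_identity(a, b)),
                     as.numeric(pairwise_identity(b, a)))
  }
})

test_that("local alignment identity agrees with an independent DP", {
  set.seed(43)
  for (k in 1:12) {
    a <- rand_dna(80)
    b <- if (k %% 2 == 0) rand_dna(80) else {
      # mutated copy: high-identity case
      nt <- strsplit(a, "")[[1]]
      idx <- sample(80, 8)
      for (i in idx) nt[i] <- sample(setdiff(NT, nt[i]), 1)
      paste(nt, collapse = "")
    }
    got <- pairwise_identity(a, b)
    want <- oracle_sw(a, b)
    expect_equal(attr(got, "score"), want$score)
    matches <- as.numeric(got) * min(nchar(a), nchar(b))
    expect_gte(matches + 1e-9, want$min_matches)
    expect_lte(matches - 1e-9, want$max_matches)
  }
})

test_that("greedy redundancy removal follows its specification", {
  trio <- c(s1 = "ACGTACGTAA", s2 = "ACGTACGTAA", s3 = "ACGTACGTAA")
  cs <- remove_redundancy(trio, tau_id = 0.9)
  expect_identical(length(cs$representatives), 1L)
  expect_setequal(cs$clusters[[cs$representatives]], names(trio))

  far <- c(a = "AAAAAAAAAA", b = "ACGTGCTAGC")
  cs2 <- remove_redundancy(far, tau_id = 0.9)
  expect_identical(length(cs2$representatives), 2L)
})

test_that("greedy clustering equals an independent greedy oracle", {
  set.seed(47)
  base <- vapply(1:12, function(i) rand_dna(sample(60:100, 1)), "")
  dup <- vapply(base[1:6], function(s) {
    nt <- strsplit(s, "")[[1]]
    i <- sample(length(nt), 2)
    nt[i] <- vapply(nt[i], function(x) sample(setdiff(NT, x), 1), "")
    paste(nt, collapse = "")
  }, "", USE.NAMES = FALSE)
  seqs <- setNames(c(base, dup), sprintf("u%02d", seq_along(c(base, dup))))
  cs <- remove_redundancy(seqs, tau_id = 0.9)
  orc <- oracle_greedy_cluster(seqs, 0.9)
  expect_identical(cs$representatives, orc$representatives)
  expect_identical(cs$clusters[order(names(cs$clusters))],
                   orc$clusters[order(names(orc$clusters))])
  # planted near-duplicates are absorbed
  expect_lte(length(cs$representatives), 12L)
})

test_that("end-to-end scan recovers planted domains and rejects decoys", {
  cfg <- synthetic_config(seed = 19,
                          domain_plant = list(n_positives = 30, n_decoys = 100,
                                              per_site_mutation_rate = 0.05))
  tr <- gen_transcriptome(cfg)
  prof <- build_profile(gen_reference_panel(seed = 19)$block)
  hits <- identify_family(tr$transcripts, prof)
  truth <- tr$truth$planted_domain_loci
  found <- merge(truth, hits, by = "transcript_id")
  ok <- found$frame.x == found$frame.y &
    found$protein_start.x == found$protein_start.y
  expect_gte(sum(ok) / nrow(truth), 0.95)
  expect_lte(sum(hits$transcript_id %in% tr$truth$decoy_ids) /
               length(tr$truth$decoy_ids), 0.01)
})
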