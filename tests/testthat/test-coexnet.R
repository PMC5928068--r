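test_that("the DE filter matches the closed-form Welch computation", {
  m <- rbind(g1 = c(1, 2, 3, 5, 6, 7, 8),
             g2 = c(4, 4, 4, 4, 4, 4, 4))
  colnames(m) <- sprintf("s%d", 1:7)
  cls <- rep(c("veg", "rep"), c(3, 4))
  res <- de_filter(m, cls, alpha = 0.05, log2_transform = FALSE)
  want <- oracle_welch(c(1, 2, 3), c(5, 6, 7, 8))
  expect_equal(res$t[1], want$t, tolerance = 1e-12)
  expect_equal(res$p[1], want$p, tolerance = 1e-12)
  # constant equal groups: t = 0, p = 1, not retained
  expect_equal(res$t[2], 0)
  expect_equal(res$p[2], 1)
  expect_false(res$retained[2])
})

test_that("the DE filter rejects designs with a class below 2 samples", {
  m <- matrix(rnorm(6), 2, 3, dimnames = list(c("a", "b"), NULL))
  expect_error(de_filter(m, c("v", "r", "r")), "at least 2")
  expect_error(de_filter(m, c("r", "r", "r")), "two levels")
})

test_that("PCC matrix equals the direct covariance formula", {
  set.seed(113)
  m <- matrix(rnorm(50 * 13), 50, 13,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  r <- pcc_matrix(m)
  expect_equal(unname(diag(r)), rep(1, 50))
  for (k in 1:10) {
    ij <- sample(50, 2)
    x <- m[ij[1], ]; y <- m[ij[2], ]
    want <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(r[ij[1], ij[2]], want, tolerance = 1e-12)
  }
  # exact negative linear relation
  m2 <- rbind(a = 1:5, b = -(1:5), c = rnorm(5))
  expect_equal(pcc_matrix(m2)["a", "b"], -1)
  expect_error(pcc_matrix(m[, 1:2]), "3 samples")
})

test_that("thresholded edge sets are nested along the grid", {
  set.seed(127)
  m <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(sprintf("g%02d", 1:30), NULL))
  r <- pcc_matrix(m)
  tt <- train_threshold(r)
  prof <- tt$profile
  expect_true(all(diff(prof$n_edges) <= 0))
  expect_true(all(diff(prof$n_nodes) <= 0))
})

test_that("threshold training matches an exhaustive grid scan", {
  # hand-built correlations with a unique interior density minimum
  ids <- sprintf("n%d", 1:6)
  r <- diag(6)
  dimnames(r) <- list(ids, ids)
  set_r <- function(i, j, v) r[i, j] <<- r[j, i] <<- v
  set_r(1, 2, 0.95); set_r(1, 3, 0.94); set_r(2, 3, 0.96)  # tight triangle
  set_r(4, 5, 0.7); set_r(5, 6, 0.65); set_r(4, 6, 0.6)    # loose strand
  tt <- train_threshold(r)
  expect_equal(tt$tau, oracle_grid_scan(r))
  expect_false(tt$empty)

  set.seed(131)
  for (k in 1:30) {
    m <- matrix(rnorm(sample(10:25, 1) * 8), ncol = 8)
    rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
    rr <- pcc_matrix(m)
    expect_equal(train_threshold(rr)$tau, oracle_grid_scan(rr))
  }
})

test_that("an everywhere-empty grid is flagged and returns the top threshold", {
  r <- diag(4); r[r == 0] <- 0.2
  dimnames(r) <- list(letters[1:4], letters[1:4])
  tt <- train_threshold(r)
  expect_true(tt$empty)
  expect_equal(tt$tau, 0.99)
})

test_that("graphs respect the edge rule and record density", {
  ids <- c("a", "b", "c", "d")
  r <- diag(4); dimnames(r) <- list(ids, ids)
  r["a", "b"] <- r["b", "a"] <- 0.9
  r["a", "c"] <- r["c", "a"] <- 0.85
  r["b", "c"] <- r["c", "b"] <- 0.8
  r["a", "d"] <- r["d", "a"] <- -0.95
  g <- build_graph(r, 0.8)
  expect_equal(igraph::ecount(g), 3)      # triangle, d excluded (signed)
  expect_equal(igraph::graph_attr(g, "density"), 1)
  g_abs <- build_graph(r, 0.8, rule = "absolute")
  expect_equal(igraph::ecount(g_abs), 4)  # anti-correlation now counts
  g_none <- build_graph(r, 0.99)
  expect_equal(igraph::ecount(g_none), 0)
})

test_that("latent-factor modules yield high within-module edge recall", {
  mods <- list(list(size = 20L, rho = 0.9, shift = 0, sign = 1L,
                    family_genes = "famA"))
  cfg <- synthetic_config(seed = 137, n_genes = 60, n_veg = 20, n_rep = 20,
                          de_fraction = 0, modules = mods, dup_cliques = 0)
  ex <- gen_expression(cfg)
  mem <- ex$truth$module_memberships$module1
  r <- pcc_matrix(log2(ex$expr))
  g <- build_graph(r, 0.7)
  within <- igraph::as_edgelist(g)
  within <- within[within[, 1] %in% mem & within[, 2] %in% mem, , drop = FALSE]
  expect_gte(nrow(within) / choose(length(mem), 2), 0.9)
})

test_that("family module extraction keeps only family-incident structure", {
  ids <- c("f1", "a1", "a2", "a3", "f2", "b1", "x1", "x2")
  r <- diag(8); dimnames(r) <- list(ids, ids)
  link <- function(i, j) r[i, j] <<- r[j, i] <<- 0.95
  link("f1", "a1"); link("f1", "a2"); link("f1", "a3")
  link("f2", "b1")
  link("x1", "x2")          # family-free edge, must vanish
  link("a1", "a2")          # adjacent-adjacent edge, must vanish
  g <- build_graph(r, 0.9)
  mods <- extract_family_modules(g, c("f1", "f2"))
  expect_length(mods, 2)
  star1 <- mods[[1]]
  expect_identical(star1$family_ids, "f1")
  expect_setequal(star1$adjacent_ids, c("a1", "a2", "a3"))
  expect_identical(star1$n_edges, 3L)
  expect_identical(unname(star1$family_degree["f1"]), 3L)
  star2 <- mods[[2]]
  expect_identical(star2$family_ids, "f2")
  expect_identical(star2$adjacent_ids, "b1")
  # modules partition the extracted subgraph; edge totals add up
  all_nodes <- c(star1$family_ids, star1$adjacent_ids,
                 star2$family_ids, star2$adjacent_ids)
  expect_identical(anyDuplicated(all_nodes), 0L)
  expect_false(any(c("x1", "x2") %in% all_nodes))
})

test_that("an isolated family gene forms a singleton module", {
  r <- diag(3); dimnames(r) <- list(c("f1", "u", "v"), c("f1", "u", "v"))
  g <- build_graph(r, 0.9)
  mods <- extract_family_modules(g, "f1")
  expect_length(mods, 1)
  expect_identical(mods[[1]]$adjacent_ids, character(0))
  expect_error(extract_family_modules(g, character(0)), "empty family")
  expect_warning(extract_family_modules(g, c("f1", "ghost")), "ghost")
})

test_that("connectivity tallies reproduce printed module arithmetic", {
  # module-1 figures: 559 adjacent genes, 234 with two or more family edges
  conn1 <- c(rep(2L, 234), rep(1L, 325))
  ms1 <- module_summary_from_counts(sprintf("fam%d", 1:7), conn1)
  t1 <- connectivity_tally(ms1, 2)
  expect_identical(t1$count, 234L)
  expect_equal(t1$percentage, 41.9)

  # module-2 figures: 297 adjacent, 158 at k >= 2 of which 55 reach 4
  conn2 <- c(rep(4L, 55), rep(2L, 103), rep(1L, 139))
  ms2 <- module_summary_from_counts(sprintf("fam%d", 1:8), conn2)
  expect_equal(connectivity_tally(ms2, 2)$percentage, 53.2)
  expect_equal(connectivity_tally(ms2, 4)$percentage, 18.5)

  ms0 <- module_summary_from_counts("famX", integer(0))
  expect_identical(connectivity_tally(ms0, 2)$count, 0L)
  expect_equal(connectivity_tally(ms0, 2)$percentage, 0)
})

test_that("module tallies equal brute-force neighbour counting", {
  set.seed(139)
  n <- 15
  ids <- c(sprintf("f%d", 1:3), sprintf("a%02d", 1:12))
  r <- diag(n); dimnames(r) <- list(ids, ids)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    v <- runif(1)
    r[i, j] <- r[j, i] <- v
  }
  g <- build_graph(r, 0.6)
  fam <- sprintf("f%d", 1:3)
  mods <- suppressWarnings(extract_family_modules(g, fam))
  adj_mat <- r >= 0.6; diag(adj_mat) <- FALSE
  for (ms in mods) {
    for (a in ms$adjacent_ids) {
      want <- sum(adj_mat[a, fam])
      for (k in c(2, 4, 5)) {
        got <- connectivity_tally(ms, k)
        brute <- sum(vapply(ms$adjacent_ids, function(x)
          sum(adj_mat[x, fam]) >= k, TRUE))
        expect_identical(got$count, as.integer(brute))
      }
    }
  }
})

test_that("tissue-specific calls follow the threshold rule exactly", {
  m <- rbind(vspec = c(5, 3, 0, 0.2, 0),
             rspec = c(0.5, 0, 2, 4, 1),
             both = c(2, 2, 2, 2, 2),
             neither = c(0.1, 0.2, 0.1, 0.3, 0.2))
  colnames(m) <- sprintf("s%d", 1:5)
  cls <- c("vegetative", "vegetative", "reproductive", "reproductive",
           "reproductive")
  ts <- tissue_specific(m, rownames(m), cls, epsilon = 1)
  got <- setNames(ts$class, ts$gene)
  expect_identical(unname(got["vspec"]), "vegetative-specific")
  expect_identical(unname(got["rspec"]), "reproductive-specific")
  expect_identical(unname(got["both"]), "none")
  expect_identical(unname(got["neither"]), "none")
  expect_warning(tissue_specific(m, c("vspec", "nope"), cls), "nope")
})

test_that("hypergeometric enrichment is exact and BH-corrected", {
  # all five sampled genes carry the term: p = 1 / choose(10, 5)
  map <- data.frame(gene = sprintf("g%d", 1:5), term = "GO:X")
  bg <- sprintf("g%d", 1:10)
  res <- hypergeom_enrichment(sprintf("g%d", 1:5), map, bg)
  expect_equal(res$p, 1 / 252)

  # zero overlap gives p = 1
  res0 <- hypergeom_enrichment(sprintf("g%d", 6:10), map, bg)
  expect_equal(res0$p, 1)

  expect_error(hypergeom_enrichment("zz", map, bg), "subset")
})

test_that("the BH step-up follows the worked example", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               c(0.03, 0.03, 0.03))
  # and the package applies it across terms
  map <- data.frame(gene = c("g1", "g2", "g1", "g3", "g4"),
                    term = c("t1", "t1", "t2", "t3", "t3"))
  res <- hypergeom_enrichment(c("g1", "g2"), map, sprintf("g%d", 1:6))
  expect_equal(sort(res$q), sort(p.adjust(res$p, method = "BH")),
               tolerance = 1e-12)
  expect_true(all(res$q >= res$p - 1e-12))
})

test_that("hypergeometric tails match exact enumeration for small universes", {
  set.seed(149)
  for (rep_ in 1:30) {
    M <- sample(5:20, 1)
    K <- sample(1:M, 1)
    n <- sample(1:M, 1)
    bg <- sprintf("g%02d", 1:M)
    with_term <- sample(bg, K)
    samp <- sample(bg, n)
    map <- data.frame(gene = with_term, term = "T")
    res <- hypergeom_enrichment(samp, map, bg)
    k <- length(intersect(samp, with_term))
    expect_equal(res$p, oracle_hyper_tail(M, K, n, k), tolerance = 1e-12)
  }
})
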