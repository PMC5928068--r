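#' Synthetic study configuration
#'
#' Bundles every tunable of the synthetic-data generators. Defaults emulate a
#' 13-sample (6 vegetative + 7 reproductive) floral transcriptome experiment
#' with group-shifted differentially expressed (DE) genes, latent-factor
#' correlation modules anchored on designated family genes, a handful of
#' near-duplicate unigene cliques (fragmented assemblies of one transcript),
#' planted ~60-aa MADS domains among decoy unigenes, a Ct model linear in log2
#' expression, and a sparse gene-to-term annotation map with one enriched term.
#'
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @param n_genes Total genes in the expression matrix (module members and
#'   duplicate cliques included).
#' @param n_veg,n_rep Vegetative / reproductive sample counts (defaults 6, 7).
#' @param de_fraction Fraction of genes carrying a vegetative-vs-reproductive
#'   group shift.
#' @param delta Log2 mean group shift for non-module DE genes.
#' @param sigma Log2-scale noise standard deviation.
#' @param modules List of module descriptors, each a list with `size`, `rho`
#'   (latent population pairwise correlation in `[0,1)`), `shift` (log2 group
#'   shift of module members; smaller than `delta` by default so modules are
#'   bound by their latent factor, not by the tissue contrast), `sign` (+1
#'   reproductive-high, -1 vegetative-high), `family_genes` (character ids of
#'   the anchoring family members) and `clade` (label used downstream).
#' @param dup_cliques,dup_size,dup_rho Number, size and latent correlation of
#'   near-duplicate unigene cliques planted among the DE background.
#' @param domain_plant List with `n_positives`, `n_decoys`,
#'   `per_site_mutation_rate` for the transcriptome generator.
#' @param ct_model List with `intercept` (cycles), `slope` (cycles per log2
#'   unit, > 0) and `noise_sd` (cycles) for the Ct generator.
#' @param annotation List with `n_terms`, `enriched_rate` (term assignment
#'   probability inside the module) and `background_rate`.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 1000L,
                             n_veg = 6L,
                             n_rep = 7L,
                             de_fraction = 0.3,
                             delta = 4,
                             sigma = 1,
                             modules = list(),
                             dup_cliques = 5L,
                             dup_size = 4L,
                             dup_rho = 0.999,
                             domain_plant = list(n_positives = 50L,
                                                 n_decoys = 200L,
                                                 per_site_mutation_rate = 0.05),
                             ct_model = list(intercept = 40,
                                             slope = 1,
                                             noise_sd = 0.15),
                             annotation = list(n_terms = 20L,
                                               enriched_rate = 0.8,
                                               background_rate = 0.05)) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_veg = as.integer(n_veg), n_rep = as.integer(n_rep),
              de_fraction = de_fraction, delta = delta, sigma = sigma,
              modules = modules, dup_cliques = as.integer(dup_cliques),
              dup_size = as.integer(dup_size), dup_rho = dup_rho,
              domain_plant = domain_plant, ct_model = ct_model,
              annotation = annotation)
  stopifnot(cfg$n_genes > 0L, cfg$n_veg > 0L, cfg$n_rep > 0L)
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) {
    stop("de_fraction must be in [0, 1]")
  }
  if (cfg$dup_rho < 0 || cfg$dup_rho >= 1) stop("dup_rho must be in [0, 1)")
  for (m in cfg$modules) {
    stopifnot(is.list(m), m$size > 0L)
    if (is.null(m$rho) || m$rho < 0 || m$rho >= 1) {
      stop("module rho must be in [0, 1)")
    }
  }
  dp <- cfg$domain_plant
  stopifnot(dp$n_positives >= 0L, dp$n_decoys >= 0L)
  if (dp$per_site_mutation_rate < 0 || dp$per_site_mutation_rate >= 1) {
    stop("per_site_mutation_rate must be in [0, 1)")
  }
  structure(cfg, class = "synthetic_config")
}

#' Two default family-anchored modules
#'
#' One vegetative-high module (SOC1-like anchors, flower-transition side) and
#' one reproductive-high module (AP3/PI-like anchors, floral-organ side),
#' mirroring the two-module structure typical of floral co-expression studies.
#'
#' @param size Members per module (anchors included).
#' @param rho Latent within-module population correlation.
#' @param shift Log2 group shift of module members.
#' @param n_family Anchoring family genes per module.
#' @return A list of two module descriptors for [synthetic_config()].
#' @export
default_modules <- function(size = 25L, rho = 0.9, shift = 1.5, n_family = 2L) {
  list(
    list(size = as.integer(size), rho = rho, shift = shift, sign = -1L,
         clade = "SOC1",
         family_genes = sprintf("FAM_SOC1_%d", seq_len(n_family))),
    list(size = as.integer(size), rho = rho, shift = shift, sign = +1L,
         clade = "AP3/PI",
         family_genes = sprintf("FAM_AP3PI_%d", seq_len(n_family)))
  )
}

#' Generate a synthetic transcriptome with planted MADS domains
#'
#' Plants mutated, back-translated copies of `consensus` at a random strand,
#' frame and offset inside random nucleotide flanks; adds decoy unigenes of
#' pure random sequence. The returned truth records every planted locus.
#'
#' @param cfg A [synthetic_config()].
#' @param consensus Amino-acid consensus to plant (length = profile length).
#' @param code Genetic code table (named character vector, codon to residue).
#' @return A list with `transcripts` (a named [Biostrings::DNAStringSet] with
#'   a `source_tag` metadata column) and `truth` (planted loci data frame plus
#'   positive/decoy id vectors).
#' @export
gen_transcriptome <- function(cfg, consensus = mads_consensus(),
                              code = Biostrings::GENETIC_CODE) {
  stopifnot(inherits(cfg, "synthetic_config"))
  aa <- .chars(consensus)
  if (!all(aa %in% AA20)) {
    stop("consensus contains non-amino-acid symbols")
  }
  set.seed(cfg$seed)
  dp <- cfg$domain_plant
  n_pos <- as.integer(dp$n_positives)
  n_dec <- as.integer(dp$n_decoys)
  rate <- dp$per_site_mutation_rate

  ids <- sprintf("tx%05d", seq_len(n_pos + n_dec))
  seqs <- character(n_pos + n_dec)
  loci <- vector("list", n_pos)
  for (i in seq_len(n_pos)) {
    prot <- .mutate_protein(consensus, rate)
    block <- .back_translate(prot, code)
    k <- sample(3L, 1L)                       # frame 1..3 on the coding strand
    strand <- sample(c("+", "-"), 1L)
    l0 <- sample(30:90, 1L)
    left_len <- l0 + ((k - 1L) - l0) %% 3L    # put the block in frame k
    right_len <- sample(30:90, 1L)
    coding <- paste0(.random_dna(left_len), block, .random_dna(right_len))
    seqs[i] <- if (strand == "-") .revcomp(coding) else coding
    loci[[i]] <- data.frame(
      transcript_id = ids[i],
      frame = if (strand == "-") -k else k,
      nt_offset = left_len,
      protein_start = (left_len - (k - 1L)) %/% 3L + 1L,
      planted_protein = prot,
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(n_dec)) {
    seqs[n_pos + i] <- .random_dna(sample(200:400, 1L))
  }
  transcripts <- Biostrings::DNAStringSet(seqs)
  names(transcripts) <- ids
  S4Vectors::mcols(transcripts)$source_tag <-
    rep(c("planted", "decoy"), c(n_pos, n_dec))
  truth <- list(
    planted_domain_loci = do.call(rbind, loci),
    positive_ids = ids[seq_len(n_pos)],
    decoy_ids = ids[n_pos + seq_len(n_dec)]
  )
  list(transcripts = transcripts, truth = truth)
}

#' Generate a synthetic expression matrix with planted DE genes and modules
#'
#' Log2 expression is `mu_g + shift_g * group + sigma * (sqrt(rho) z_s +
#' sqrt(1 - rho) e_gs)` where `group` is -1/2 for vegetative and +1/2 for
#' reproductive samples, `z_s` is a per-module latent factor shared across the
#' module's genes, and `e_gs` is gene-level noise; expression is `2^log2`, so
#' all values are positive and within-module population correlation equals
#' `rho`. Non-module DE genes get shift `+/- delta` with random sign;
#' near-duplicate cliques are DE groups with latent correlation `dup_rho`.
#'
#' @param cfg A [synthetic_config()]. Module member ids must be disjoint.
#' @return A list with `expr` (genes x samples matrix), `samples` (data frame
#'   with `sample`, `class`, `stage`) and `truth` (`de_gene_ids`, `de_sign`,
#'   `module_memberships`, `dup_cliques`, `gene_clades`).
#' @export
gen_expression <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 1L)
  n_fam <- sum(vapply(cfg$modules, function(m) length(m$family_genes), 1L))
  fam_ids <- unlist(lapply(cfg$modules, `[[`, "family_genes"))
  if (anyDuplicated(fam_ids)) stop("modules overlap: duplicated family gene ids")
  mod_sizes <- vapply(cfg$modules, function(m) as.integer(m$size), 1L)
  n_dup_total <- cfg$dup_cliques * cfg$dup_size
  if (sum(mod_sizes) + n_dup_total > cfg$n_genes) {
    stop("module sizes (plus duplicate cliques) exceed n_genes")
  }

  n_fill <- cfg$n_genes - n_fam
  gene_ids <- c(fam_ids, sprintf("g%05d", seq_len(n_fill)))
  n_samp <- cfg$n_veg + cfg$n_rep
  samples <- data.frame(
    sample = c(sprintf("V%02d", seq_len(cfg$n_veg)),
               sprintf("R%02d", seq_len(cfg$n_rep))),
    class = rep(c("vegetative", "reproductive"), c(cfg$n_veg, cfg$n_rep)),
    stringsAsFactors = FALSE
  )
  samples$stage <- samples$sample
  group <- ifelse(samples$class == "reproductive", 0.5, -0.5)

  # assign module members: anchors plus the next unassigned filler genes
  membership <- rep(NA_character_, cfg$n_genes)
  names(membership) <- gene_ids
  next_free <- n_fam + 1L
  module_memberships <- list()
  gene_clades <- character(0)
  signs <- integer(length(cfg$modules))
  for (mi in seq_along(cfg$modules)) {
    m <- cfg$modules[[mi]]
    extra <- m$size - length(m$family_genes)
    if (extra < 0L) stop("module size smaller than its family gene count")
    members <- c(m$family_genes,
                 gene_ids[seq.int(next_free, length.out = extra)])
    next_free <- next_free + extra
    if (any(!is.na(membership[members]))) stop("modules overlap")
    membership[members] <- sprintf("module%d", mi)
    module_memberships[[sprintf("module%d", mi)]] <- members
    clade <- if (is.null(m$clade)) sprintf("clade%d", mi) else m$clade
    gene_clades[m$family_genes] <- clade
    signs[mi] <- if (is.null(m$sign)) c(-1L, 1L)[1L + (mi %% 2L == 0L)] else m$sign
  }
  dup_memberships <- list()
  for (di in seq_len(cfg$dup_cliques)) {
    members <- gene_ids[seq.int(next_free, length.out = cfg$dup_size)]
    next_free <- next_free + cfg$dup_size
    membership[members] <- sprintf("dup%d", di)
    dup_memberships[[sprintf("dup%d", di)]] <- members
  }

  # DE status: module and duplicate-clique genes are group-shifted by design;
  # the remainder of round(de_fraction * n_genes) comes from free genes.
  n_de <- round(cfg$de_fraction * cfg$n_genes)
  shift <- numeric(cfg$n_genes)
  names(shift) <- gene_ids
  for (mi in seq_along(cfg$modules)) {
    m <- cfg$modules[[mi]]
    sh <- if (is.null(m$shift)) cfg$delta else m$shift
    shift[module_memberships[[mi]]] <- signs[mi] * sh
  }
  for (di in seq_len(cfg$dup_cliques)) {
    shift[dup_memberships[[di]]] <- sample(c(-1, 1), 1L) * cfg$delta
  }
  n_structured <- sum(mod_sizes) + n_dup_total
  n_bg_de <- max(0L, n_de - n_structured)
  free <- gene_ids[is.na(membership)]
  bg_de <- head(free, n_bg_de)
  shift[bg_de] <- sample(c(-1, 1), length(bg_de), replace = TRUE) * cfg$delta

  mu <- runif(cfg$n_genes, 3, 8)
  log2x <- matrix(rnorm(cfg$n_genes * n_samp, sd = 1),
                  nrow = cfg$n_genes, dimnames = list(gene_ids, samples$sample))
  groups <- c(module_memberships, dup_memberships)
  rhos <- c(vapply(cfg$modules, `[[`, numeric(1), "rho"),
            rep(cfg$dup_rho, cfg$dup_cliques))
  for (gi in seq_along(groups)) {
    z <- rnorm(n_samp)
    rho <- rhos[gi]
    mem <- groups[[gi]]
    log2x[mem, ] <- sqrt(rho) * matrix(z, nrow = length(mem), ncol = n_samp,
                                       byrow = TRUE) +
      sqrt(1 - rho) * log2x[mem, , drop = FALSE]
  }
  log2x <- mu + outer(shift, group) + cfg$sigma * log2x
  expr <- 2^log2x
  dimnames(expr) <- list(gene_ids, samples$sample)

  de_ids <- gene_ids[shift != 0]
  list(expr = expr,
       samples = samples,
       truth = list(de_gene_ids = de_ids,
                    de_sign = sign(shift[de_ids]),
                    module_memberships = module_memberships,
                    dup_cliques = dup_memberships,
                    gene_clades = gene_clades))
}

#' Generate a qRT-PCR Ct table from an expression matrix
#'
#' `Ct = a - b * log2(expression + 1) + noise`. Reference genes are given
#' constant expression across samples (their across-sample mean) before the
#' model is applied, so at zero noise their Ct is identical in every sample.
#' Ct values above `detect_limit` are masked as not detected.
#'
#' @param cfg A [synthetic_config()] (uses `ct_model` and `seed`).
#' @param expr Genes x samples expression matrix (e.g. from
#'   [gen_expression()]).
#' @param ref_ids Reference gene ids; must be rows of `expr`.
#' @param samples Optional sample annotation data frame.
#' @param detect_limit Ct above which a measurement is masked (default 40).
#' @return A `ct_table` (see [new_ct_table()]) plus a `truth` attribute with
#'   the noise-free reference Ct offsets.
#' @export
gen_ct_table <- function(cfg, expr, ref_ids, samples = NULL,
                         detect_limit = 40) {
  stopifnot(inherits(cfg, "synthetic_config"), is.matrix(expr))
  cm <- cfg$ct_model
  if (cm$slope <= 0) stop("ct_model slope must be positive")
  if (!all(ref_ids %in% rownames(expr))) {
    stop("reference gene ids missing from the expression matrix: ",
         paste(setdiff(ref_ids, rownames(expr)), collapse = ", "))
  }
  set.seed(cfg$seed + 2L)
  e <- expr
  for (r in ref_ids) e[r, ] <- mean(expr[r, ])
  ct <- cm$intercept - cm$slope * log2(e + 1)
  if (cm$noise_sd > 0) {
    noise <- matrix(rnorm(length(ct), sd = cm$noise_sd), nrow = nrow(ct))
    noise[rownames(ct) %in% ref_ids, ] <- 0  # references stay stable
    ct <- ct + noise
  }
  detected <- ct <= detect_limit
  detected[rownames(ct) %in% ref_ids, ] <- TRUE
  tab <- new_ct_table(ct, ref_ids, samples = samples, detected = detected)
  attr(tab, "truth") <- list(
    reference_ct_offsets = setNames(
      cm$intercept - cm$slope * log2(vapply(ref_ids, function(r)
        mean(expr[r, ]), numeric(1)) + 1), ref_ids)
  )
  tab
}

#' Generate a gene-to-term annotation map with one enriched term
#'
#' Term `T001` is assigned to the given module genes at `enriched_rate` and to
#' all other genes at `background_rate`; every other term is assigned at
#' `background_rate` throughout.
#'
#' @param cfg A [synthetic_config()] (uses `annotation` and `seed`).
#' @param module_genes Genes in which the designated term is enriched.
#' @param universe All gene ids; must be non-empty and contain `module_genes`.
#' @return A list with `map` (data frame `gene`, `term`) and `truth`
#'   (`enriched_term`).
#' @export
gen_annotation <- function(cfg, module_genes, universe) {
  stopifnot(inherits(cfg, "synthetic_config"))
  an <- cfg$annotation
  if (an$n_terms < 2L) stop("annotation n_terms must be >= 2")
  if (length(universe) == 0L) stop("empty gene universe")
  stopifnot(all(module_genes %in% universe))
  set.seed(cfg$seed + 3L)
  terms <- sprintf("T%03d", seq_len(an$n_terms))
  rows <- list()
  for (tm in terms) {
    rate <- rep(an$background_rate, length(universe))
    if (tm == terms[1L]) rate[universe %in% module_genes] <- an$enriched_rate
    hit <- runif(length(universe)) < rate
    if (any(hit)) {
      rows[[tm]] <- data.frame(gene = universe[hit], term = tm,
                               stringsAsFactors = FALSE)
    }
  }
  map <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(map = map, truth = list(enriched_term = terms[1L]))
}

#' Generate a labelled clade reference panel of domain blocks
#'
#' Each clade gets a mutated copy of the consensus as its centre
#' (`between_rate` per site); panel entries are species-tagged copies of the
#' centre mutated at `within_rate`. Codon blocks are deterministic
#' back-translations of the protein blocks.
#'
#' @param seed Integer seed.
#' @param consensus Protein consensus (see [mads_consensus()]).
#' @param clades Clade labels; default is the 12 MIKC clades plus an
#'   MIKC*-outgroup label.
#' @param species Species tags; one entry per species per clade replicate.
#' @param n_per_species Entries per clade per species.
#' @param between_rate,within_rate Per-site mutation rates between clade
#'   centres and within a clade.
#' @return Data frame `id`, `species`, `clade`, `block`, `codons`.
#' @export
gen_reference_panel <- function(seed = 1L, consensus = mads_consensus(),
                                clades = mikc_clades(),
                                species = c("Ath", "Fve"),
                                n_per_species = 2L,
                                between_rate = 0.3, within_rate = 0.05) {
  set.seed(seed + 4L)
  rows <- list()
  for (cl in clades) {
    centre <- .mutate_protein(consensus, between_rate)
    for (sp in species) {
      for (i in seq_len(n_per_species)) {
        block <- .mutate_protein(centre, within_rate)
        id <- sprintf("%s_%s_%d", sp, gsub("[^A-Za-z0-9]", "", cl), i)
        rows[[id]] <- data.frame(id = id, species = sp, clade = cl,
                                 block = block,
                                 codons = .back_translate(block),
                                 stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' The 12 MIKC clade labels (plus outgroup)
#'
#' @param outgroup Include the MIKC*-outgroup label.
#' @return Character vector of clade labels.
#' @export
mikc_clades <- function(outgroup = TRUE) {
  cl <- c("AP1/FUL", "AP3/PI", "AG", "SEP", "SOC1", "SVP", "AGL6", "AGL12",
          "AGL15", "AGL17", "FLC", "BS")
  if (outgroup) c(cl, "MIKC*-outgroup") else cl
}
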