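#' Pipeline configuration
#'
#' One flat configuration for the end-to-end synthetic analysis. Every
#' analysis parameter with a study-level default is surfaced by name
#' (identity cutoff 0.90, significance level 0.05, correlation grid step
#' 0.01, and so on).
#'
#' @param seed Integer seed driving every stage.
#' @param outdir Output directory.
#' @param stages Stages to run, in dependency order, a subset of
#'   `c("synth", "identify", "classify", "domstats", "express", "network")`.
#' @param synth A [synthetic_config()]; its seed is overridden by `seed`.
#' @param tau_id Redundancy identity cutoff (default 0.90).
#' @param bit_threshold_frac Profile acceptance threshold fraction.
#' @param m Nearest-neighbour vote size for clade assignment.
#' @param d_accept Maximum nearest-reference distance for family acceptance.
#' @param d_max Maximum p-distance for paralog pairs.
#' @param alpha DE filter level.
#' @param grid Correlation threshold grid.
#' @param edge_rule `"signed"` or `"absolute"`.
#' @param epsilon Detection / tissue-specificity threshold.
#' @param K Cluster count for expression clustering.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            outdir = tempfile("florafam_run_"),
                            stages = c("synth", "identify", "classify",
                                       "domstats", "express", "network"),
                            synth = synthetic_config(seed = seed,
                                                     modules = default_modules()),
                            tau_id = 0.90,
                            bit_threshold_frac = 0.6,
                            m = 3L,
                            d_accept = 0.4,
                            d_max = 0.15,
                            alpha = 0.05,
                            grid = seq(0.50, 0.99, by = 0.01),
                            edge_rule = "signed",
                            epsilon = 1,
                            K = 3L) {
  known <- c("synth", "identify", "classify", "domstats", "express", "network")
  if (!all(stages %in% known)) {
    stop("unknown stage: ", paste(setdiff(stages, known), collapse = ", "))
  }
  synth$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), outdir = outdir, stages = stages,
                 synth = synth, tau_id = tau_id,
                 bit_threshold_frac = bit_threshold_frac, m = as.integer(m),
                 d_accept = d_accept, d_max = d_max, alpha = alpha,
                 grid = grid, edge_rule = edge_rule, epsilon = epsilon,
                 K = as.integer(K)),
            class = "pipeline_config")
}

.need_stage <- function(state, stage, needed_by) {
  if (is.null(state[[stage]])) {
    stop("stage '", needed_by, "' requires stage '", stage,
         "' to have run first")
  }
  state[[stage]]
}

#' Run the pipeline end-to-end
#'
#' Executes the requested stages in dependency order (synth, identify,
#' classify, domstats, express, network), writes per-stage outputs under
#' `cfg$outdir`, and a machine-readable `summary.json`. Identical
#' configuration and seed give an identical summary.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with `summary` and the output directory.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  state <- list()
  summary <- list(seed = cfg$seed,
                  parameters = list(tau_id = cfg$tau_id,
                                    bit_threshold_frac = cfg$bit_threshold_frac,
                                    m = cfg$m, d_accept = cfg$d_accept,
                                    d_max = cfg$d_max, alpha = cfg$alpha,
                                    grid = range(cfg$grid),
                                    edge_rule = cfg$edge_rule,
                                    epsilon = cfg$epsilon, K = cfg$K))

  if ("synth" %in% cfg$stages) {
    tr <- gen_transcriptome(cfg$synth)
    panel <- gen_reference_panel(seed = cfg$seed)
    ex <- gen_expression(cfg$synth)
    refs <- utils::tail(setdiff(rownames(ex$expr), ex$truth$de_gene_ids), 3L)
    ct <- gen_ct_table(cfg$synth, ex$expr, ref_ids = refs,
                       samples = ex$samples)
    state$synth <- list(tr = tr, panel = panel, ex = ex, ct = ct, refs = refs)
    write_fasta(tr$transcripts, file.path(cfg$outdir, "transcripts.fasta"))
    write_matrix_tsv(ex$expr, file.path(cfg$outdir, "expression.tsv"))
    write.table(ex$samples, file.path(cfg$outdir, "samples.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_ct_table(ct, file.path(cfg$outdir, "ct.tsv"))
    jsonlite::write_json(tr$truth["positive_ids"],
                         file.path(cfg$outdir, "truth_domains.json"))
    summary$synth <- list(n_transcripts = length(tr$transcripts),
                          n_genes = nrow(ex$expr),
                          n_samples = ncol(ex$expr))
  }

  if ("identify" %in% cfg$stages) {
    sy <- .need_stage(state, "synth", "identify")
    profile <- build_profile(sy$panel$block,
                             bit_threshold_frac = cfg$bit_threshold_frac)
    hits <- identify_family(sy$tr$transcripts, profile)
    nr <- if (nrow(hits) > 0L) {
      remove_redundancy(
        as.character(sy$tr$transcripts[hits$transcript_id]),
        tau_id = cfg$tau_id)
    } else NULL
    state$identify <- list(profile = profile, hits = hits, nr = nr)
    write.table(hits[, c("transcript_id", "frame", "protein_start", "score")],
                file.path(cfg$outdir, "domain_hits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(nr)) write_cluster_tsv(nr, file.path(cfg$outdir, "clusters.tsv"))
    blocks <- setNames(hits$block_protein, hits$transcript_id)
    write_fasta(setNames(
      hits$block_protein,
      sprintf("%s|%d|%d", hits$transcript_id, hits$frame, hits$protein_start)),
      file.path(cfg$outdir, "domain_blocks.fasta"), type = "aa")
    summary$identify <- list(n_hits = nrow(hits),
                             n_nonredundant = if (is.null(nr)) 0L else
                               length(nr$representatives))
  }

  if ("classify" %in% cfg$stages) {
    idf <- .need_stage(state, "identify", "classify")
    sy <- state$synth
    reps <- idf$nr$representatives
    blocks <- setNames(idf$hits$block_protein,
                       idf$hits$transcript_id)[reps]
    cls <- classify_blocks(as.list(blocks), sy$panel, m = cfg$m,
                           d_accept = cfg$d_accept)
    tree <- NULL
    if (length(blocks) + nrow(sy$panel) >= 3L) {
      all_blocks <- c(blocks, setNames(sy$panel$block, sy$panel$id))
      tree <- nj_tree(p_distance_matrix(all_blocks))
      ape::write.tree(tree, file.path(cfg$outdir, "nj_tree.nwk"))
    }
    accepted <- cls[cls$accepted, , drop = FALSE]
    par_pairs <- if (nrow(accepted) >= 2L) {
      find_paralog_pairs(blocks[accepted$query_id], d_max = cfg$d_max)
    } else data.frame()
    state$classify <- list(cls = cls, blocks = blocks, tree = tree)
    write.table(cls, file.path(cfg$outdir, "clade_assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    counts <- table(accepted$label)
    summary$classify <- list(n_classified = nrow(cls),
                             n_accepted = nrow(accepted),
                             clade_counts = as.list(counts),
                             n_paralog_pairs = nrow(par_pairs))
  }

  if ("domstats" %in% cfg$stages) {
    cl <- .need_stage(state, "classify", "domstats")
    idf <- state$identify
    sy <- state$synth
    hits <- idf$hits
    per_clade <- list()
    accepted <- cl$cls[cl$cls$accepted, , drop = FALSE]
    for (lab in sort(unique(accepted$label))) {
      qids <- accepted$query_id[accepted$label == lab]
      q_blocks <- setNames(
        hits$block_protein[match(qids, hits$transcript_id)], qids)
      ref <- sy$panel[sy$panel$clade == lab, , drop = FALSE]
      all_blocks <- c(q_blocks, setNames(ref$block, ref$id))
      groups <- rep(c("focal", "other"), c(length(q_blocks), nrow(ref)))
      entry <- list(n_members = length(qids))
      if (length(all_blocks) >= 2L) {
        entry$mean_divergence <-
          mean(site_divergence(all_blocks)$rates, na.rm = TRUE)
      }
      if (length(q_blocks) >= 1L && nrow(ref) >= 1L) {
        lss <- lineage_specific_sites(all_blocks, groups)
        entry$n_lineage_specific_sites <- nrow(lss)
      }
      codons <- setNames(hits$block_codons[match(qids, hits$transcript_id)],
                         qids)
      if (length(codons) >= 2L) {
        kk <- tryCatch(clade_mean_kaks(codons), error = function(e) NULL)
        if (!is.null(kk)) {
          entry$mean_ka <- kk$mean_dn
          entry$mean_ks <- kk$mean_ds
          entry$mean_omega <- kk$mean_omega
        }
      }
      per_clade[[lab]] <- entry
    }
    state$domstats <- per_clade
    summary$domstats <- per_clade
  }

  if ("express" %in% cfg$stages) {
    sy <- .need_stage(state, "synth", "express")
    re <- relative_expression(sy$ct)
    fc <- stage_fold_change(re, stage_order = sy$ex$samples$stage)
    fam <- unlist(lapply(cfg$synth$modules, `[[`, "family_genes"))
    det <- NULL
    if (length(fam) > 0L) {
      det <- detection_summary(sy$ex$expr,
                               sy$ex$truth$gene_clades,
                               epsilon = cfg$epsilon)
      cl_genes <- fam[fam %in% rownames(re$values)]
      cc <- if (length(cl_genes) >= cfg$K) {
        correlation_cluster(re$values[cl_genes, , drop = FALSE], K = cfg$K)
      } else NULL
      state$express <- list(re = re, fc = fc, det = det, cc = cc)
    } else {
      state$express <- list(re = re, fc = fc)
    }
    write_matrix_tsv(re$values, file.path(cfg$outdir, "relative_expression.tsv"))
    write_matrix_tsv(fc$fc, file.path(cfg$outdir, "stage_fold_changes.tsv"))
    summary$express <- list(
      n_genes = nrow(re$values),
      pct_clades_detected = if (!is.null(det)) det$pct_clades_detected else NA)
  }

  if ("network" %in% cfg$stages) {
    sy <- .need_stage(state, "synth", "network")
    dfres <- de_filter(sy$ex$expr, sy$ex$samples$class, alpha = cfg$alpha)
    kept <- dfres$gene[dfres$retained]
    summary$network <- list(n_de = length(kept))
    if (length(kept) >= 2L) {
      # correlations on the same variance-stabilised scale as the DE filter
      r <- pcc_matrix(log2(sy$ex$expr[kept, , drop = FALSE] + 1))
      tt <- train_threshold(r, grid = cfg$grid, rule = cfg$edge_rule)
      g <- build_graph(r, tt$tau, rule = cfg$edge_rule)
      fam <- unlist(lapply(cfg$synth$modules, `[[`, "family_genes"))
      mods <- if (length(fam) > 0L && any(fam %in% igraph::V(g)$name)) {
        suppressWarnings(extract_family_modules(g, fam))
      } else list()
      adj <- unique(unlist(lapply(mods, `[[`, "adjacent_ids")))
      ts <- if (length(adj) > 0L) {
        tissue_specific(sy$ex$expr, adj, sy$ex$samples$class,
                        epsilon = cfg$epsilon)
      } else data.frame()
      enr <- NULL
      if (length(adj) > 0L) {
        ann <- gen_annotation(cfg$synth,
                              module_genes = adj,
                              universe = rownames(sy$ex$expr))
        enr <- hypergeom_enrichment(adj, ann$map, rownames(sy$ex$expr))
        write.table(enr, file.path(cfg$outdir, "enrichment.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      write_graph_files(g,
                        path_graphml = file.path(cfg$outdir, "network.graphml"),
                        path_edges = file.path(cfg$outdir, "edges.tsv"))
      state$network <- list(de = dfres, r = r, tt = tt, g = g, mods = mods)
      summary$network <- c(summary$network, list(
        tau = tt$tau,
        density_at_tau =
          tt$profile$density[tt$profile$tau == tt$tau],
        modules = lapply(mods, function(m) list(
          family = m$family_ids,
          n_adjacent = length(m$adjacent_ids),
          n_edges = m$n_edges,
          pct_ge2 = connectivity_tally(m, 2L)$percentage)),
        n_tissue_specific = if (nrow(ts) > 0L)
          sum(ts$class != "none") else 0L,
        top_term = if (!is.null(enr) && nrow(enr) > 0L) enr$term[1L] else NA))
    }
  }

  summary_path <- file.path(cfg$outdir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(list(summary = summary, outdir = cfg$outdir, state = state))
}
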