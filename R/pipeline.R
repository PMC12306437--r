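#' Pipeline configuration
#'
#' Collects every threshold of the stage-synergy pipeline in one object:
#' the >10-cases-per-stage rule, the Kruskal-Wallis retention alpha, the
#' per-stage correlation alpha behind the adjusted PCC, the permutation
#' trial count and its empirical alpha, and the Spearman / Fisher /
#' differential-expression alphas of the downstream modules.
#'
#' @param outdir Output directory for all result files.
#' @param seed Master seed; every random step derives from it.
#' @param sim A [synergy_sim_config()] used when `input_dir` is `NULL`
#'   (the pipeline then generates its own inputs and writes them under
#'   `outdir/inputs`).
#' @param input_dir Optional directory of input TSVs laid out as written by
#'   [write_study_tsv()].
#' @param min_cases Keep stages with strictly more than this many samples
#'   (default 10).
#' @param kw_alpha Kruskal-Wallis retention threshold (default 0.05).
#' @param sig_alpha Per-stage Pearson significance for the adjusted
#'   correlation (default 0.05).
#' @param perm_B Permutation trials per pair (default 1000).
#' @param perm_alpha Empirical p-value threshold (default 0.05).
#' @param spearman_alpha,fisher_alpha,diff_alpha Module thresholds
#'   (default 0.05 each).
#' @param early_stages Stages counted as early for pattern classification
#'   (default `c(1, 2)`); all other surviving stages are advanced.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            sim = synergy_sim_config(seed = seed),
                            input_dir = NULL,
                            min_cases = 10, kw_alpha = 0.05,
                            sig_alpha = 0.05, perm_B = 1000,
                            perm_alpha = 0.05, spearman_alpha = 0.05,
                            fisher_alpha = 0.05, diff_alpha = 0.05,
                            early_stages = c(1, 2)) {
  alphas <- c(kw_alpha, sig_alpha, perm_alpha, spearman_alpha, fisher_alpha,
              diff_alpha)
  if (any(alphas <= 0 | alphas >= 1)) {
    stop("all alpha thresholds must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(perm_B >= 1, min_cases >= 1)
  structure(list(outdir = outdir, seed = as.integer(seed), sim = sim,
                 input_dir = input_dir, min_cases = min_cases,
                 kw_alpha = kw_alpha, sig_alpha = sig_alpha,
                 perm_B = as.integer(perm_B), perm_alpha = perm_alpha,
                 spearman_alpha = spearman_alpha,
                 fisher_alpha = fisher_alpha, diff_alpha = diff_alpha,
                 early_stages = early_stages),
            class = "pipeline_config")
}

# small deterministic FNV-1a-style hash of the configuration, for output
# provenance headers
config_hash <- function(config) {
  config <- unclass(config)
  config$outdir <- NULL   # paths are ancillary: equal settings hash equal
  config$input_dir <- NULL
  codes <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 2166136261
  for (cc in codes) h <- ((bitwXor(as.integer(h %% 2^31), cc)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

read_study_inputs <- function(dir) {
  p <- function(f) file.path(dir, f)
  expr <- read_expression_tsv(p("expression.tsv"), p("clinical.tsv"),
                              p("gene_catalog.tsv"))
  cs <- read_tsv_quiet(p("cell_scores.tsv"))
  cell_scores <- as.matrix(cs[, -1])
  rownames(cell_scores) <- cs$cell_type
  spat <- read_spatial_tsv(p("spatial_counts.tsv"), p("spatial_coords.tsv"))
  list(expr = expr,
       ppi = read_tsv_quiet(p("ppi.tsv")),
       catalog = read_tsv_quiet(p("interactions.tsv")),
       icps = read_gene_list(p("icp_genes.txt")),
       cell_scores = cell_scores,
       spatial = list(counts = spat$counts, coords = spat$coords,
                      markers = read_tsv_quiet(p("spatial_markers.tsv")),
                      truth = read_tsv_quiet(p("spatial_truth.tsv"))),
       survival = read_tsv_quiet(p("survival.tsv")),
       truth = read_tsv_quiet(p("pair_truth.tsv")))
}

spatial_test_pairs <- function(spatial, n_background_pairs = 10) {
  bg <- grep("^BG", colnames(spatial$counts), value = TRUE)
  planted <- tibble::tibble(entity1 = spatial$truth$gene1,
                            entity2 = spatial$truth$gene2)
  k <- min(n_background_pairs, floor(length(bg) / 2))
  if (k > 0) {
    planted <- dplyr::bind_rows(
      planted,
      tibble::tibble(entity1 = bg[2 * seq_len(k) - 1], entity2 = bg[2 * seq_len(k)])
    )
  }
  planted
}

#' Run the full stage-synergy pipeline
#'
#' Executes, in order: input simulation (or loading), stage filtering,
#' candidate-pair construction, ssLIss scoring with permutation
#' significance, co-expression pattern classification, functional-lncRNA
#' enrichment, immune-cell association, spatial co-occurrence calling and
#' final-stage signature survival stratification. Every result table is
#' written to `config$outdir` as TSV with a provenance header (seed and
#' configuration hash), plus a machine-readable `report.json`. Identical
#' configuration and seed reproduce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The run report, invisibly (a list of per-stage counts, seeds and
#'   thresholds).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- paste0("stagesynergy ",
                as.character(utils::packageVersion("stagesynergy")),
                " seed=", config$seed, " config_hash=", config_hash(config))
  emit <- function(df, file) {
    write_tsv_commented(df, file.path(config$outdir, file), hdr)
  }

  simulated <- is.null(config$input_dir)
  study <- if (simulated) {
    st <- simulate_study(config$sim)
    write_study_tsv(st, file.path(config$outdir, "inputs"))
    st
  } else {
    read_study_inputs(config$input_dir)
  }

  expr_f <- filter_stages(study$expr, config$min_cases)
  stages <- sort(unique(stage_vector(expr_f)))
  advanced <- setdiff(stages, config$early_stages)

  candidates <- build_candidates(expr_f, study$ppi, study$catalog,
                                 study$icps, config$kw_alpha)
  emit(candidates, "candidates.tsv")

  scan <- score_synergy(expr_f, candidates, B = config$perm_B,
                        sig_alpha = config$sig_alpha,
                        perm_alpha = config$perm_alpha, seed = config$seed)
  emit(scan$results, "synergy.tsv")
  emit(scan$profiles, "stage_correlations.tsv")

  calls <- classify_patterns(scan, early_stages = config$early_stages,
                             advanced_stages = advanced)
  emit(calls, "patterns.tsv")
  emit(stage_multiplicity(scan), "stage_multiplicity.tsv")
  if (nrow(calls)) emit(pattern_gene_summary(calls), "pattern_genes.tsv")

  sig <- scan$results[scan$results$significant, ]
  sig_genes <- unique(c(sig$lncrna, sig$mrna))

  # enrichment of identified lncRNAs against the functional catalogue
  # (in simulation mode: the planted specific-pair lncRNAs)
  lnc_universe <- study$expr$gene_class$gene[
    study$expr$gene_class$class == "lncRNA"]
  functional <- if (!is.null(study$truth)) {
    study$truth$lncrna[study$truth$planted_class == "specific"]
  } else {
    character()
  }
  identified_lnc <- unique(sig$lncrna)
  enrich <- if (length(functional) && length(identified_lnc)) {
    hypergeom_enrichment(lnc_universe, functional, identified_lnc)
  } else {
    tibble::tibble(N = integer(), m = integer(), n = integer(),
                   k = integer(), p = double())
  }
  emit(enrich, "enrichment.tsv")

  cell_scores_f <- study$cell_scores[, colnames(expr_f$values), drop = FALSE]
  assoc <- stage_spearman(expr_f, cell_scores_f, sig_genes,
                          alpha = config$spearman_alpha, cancer = "SIM")
  emit(assoc, "cell_associations.tsv")
  emit(cancer_stage_cell_processes(assoc), "cell_processes.tsv")
  emit(direction_consistency(assoc, min_combos = 1), "cell_consistency.tsv")
  early_samples <- expr_f$sample_stage$sample[
    expr_f$sample_stage$stage %in% config$early_stages]
  adv_samples <- setdiff(expr_f$sample_stage$sample, early_samples)
  cell_diff <- stage_difference_test(cell_scores_f, early_samples,
                                     adv_samples)
  emit(cell_diff, "cell_stage_difference.tsv")

  spatial_calls <- call_pairs(spatial_test_pairs(study$spatial),
                              counts = study$spatial$counts,
                              alpha = config$fisher_alpha)
  emit(spatial_calls, "spatial_calls.tsv")

  last <- max(stages)
  last_genes <- unique(unlist(sig[!is.na(sig$specific_stage) &
                                    sig$specific_stage == last,
                                  c("lncrna", "mrna")]))
  surv_summaries <- list()
  if (length(last_genes)) {
    sets <- stage_differential_sets(expr_f, last_genes, target_stage = last,
                                    alpha = config$diff_alpha)
    for (dir_label in c("up", "down")) {
      gs <- sets[[dir_label]]
      if (length(gs) == 0) next
      ss <- signature_survival(expr_f, gs, study$survival,
                               direction = dir_label,
                               set_id = paste0("stage", last, "_", dir_label))
      emit(tidy(ss), paste0("survival_scores_", dir_label, ".tsv"))
      surv_summaries[[dir_label]] <- glance(ss)
    }
  }
  surv_tbl <- dplyr::bind_rows(surv_summaries)
  emit(surv_tbl, "survival_logrank.tsv")

  report <- list(
    package_version = as.character(utils::packageVersion("stagesynergy")),
    seed = config$seed,
    config_hash = config_hash(config),
    simulated_inputs = simulated,
    thresholds = config[c("min_cases", "kw_alpha", "sig_alpha", "perm_B",
                          "perm_alpha", "spearman_alpha", "fisher_alpha",
                          "diff_alpha")],
    stages_kept = stages,
    counts = list(
      samples = ncol(expr_f$values),
      candidates = nrow(candidates),
      pairs_scored = nrow(scan$results),
      pairs_significant = nrow(sig),
      pattern_calls = nrow(calls),
      cell_associations = nrow(assoc),
      spatial_pairs_tested = nrow(spatial_calls),
      spatial_cooccurrence = sum(spatial_calls$call == "cooccurrence"),
      spatial_exclusivity = sum(spatial_calls$call == "exclusivity"),
      survival_signatures = nrow(surv_tbl)
    )
  )
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
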