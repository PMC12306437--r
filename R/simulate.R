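#' Configuration for the synthetic study generator
#'
#' Defines a synthetic multi-stage cohort with planted ground truth for every
#' input the pipeline consumes: stage-labelled expression with pairs that
#' co-express in exactly one stage (planted "synergy"), pairs equally
#' correlated in all stages, uncorrelated decoy pairs, a PPI network anchoring
#' each catalogued mRNA to an immune-checkpoint (ICP) gene, cell-type
#' enrichment scores with planted monotone gene associations, spatial spots
#' with planted co-occurring and mutually exclusive gene pairs, and survival
#' times whose hazard is log-linear in a planted signature score.
#'
#' Defaults describe the reference simulation used throughout the package's
#' own validation: 3 stages of 150 samples, 20 stage-specific pairs at
#' r = 0.8, 20 uniform pairs at r = 0.6 and 200 null pairs.
#'
#' @param n_stages Number of tumour stages (>= 2).
#' @param samples_per_stage Integer vector of length `n_stages`, samples in
#'   each stage.
#' @param n_lncrna,n_mrna,n_icp Gene-universe sizes; the last `n_icp` mRNAs
#'   are flagged as immune-checkpoint genes.
#' @param n_planted_specific Pairs correlated in exactly one stage.
#' @param planted_r Pearson correlation of a specific pair within its active
#'   stage, in (0, 1).
#' @param n_planted_uniform Pairs equally correlated in every stage.
#' @param uniform_r Their correlation, in (0, 1).
#' @param n_null_pairs Catalogued but uncorrelated decoy pairs.
#' @param stage_shift Deterministic per-stage mean offset (in SD units per
#'   stage step) applied to each catalogued pair's lncRNA so that pairs are
#'   stage-differential and survive the Kruskal-Wallis filter. Set to 0 for a
#'   cohort with no stage structure at all.
#' @param noise_sd Residual SD of the planted cell-score associations.
#' @param n_decoy_edges Random PPI edges beyond the anchoring edges.
#' @param n_decoy_pairs Catalogue pairs whose mRNA is kept away from every
#'   ICP neighbourhood (they must be filtered out downstream).
#' @param n_cell_types Number of simulated cell types.
#' @param n_planted_cell_assoc Planted monotone (gene, cell type)
#'   associations, alternating positive/negative sign.
#' @param spatial List: `grid_side` (spots per grid edge), `n_cooccur`,
#'   `n_exclusive`, `n_background_genes`, `background_rate` (presence
#'   probability outside a planted region), `region_rate` (inside),
#'   `lambda` (Poisson mean of positive counts), `n_cell_types`,
#'   `markers_per_type`.
#' @param survival List: `baseline_hazard` (events/day), `effect`
#'   (log-hazard per unit signature score), `censor_rate` (independent
#'   exponential censoring, events/day).
#' @param seed Master RNG seed; each generator draws from its own stream at a
#'   fixed offset from it, so outputs are reproducible and independent.
#' @return A validated `synergy_sim_config` list.
#' @export
synergy_sim_config <- function(n_stages = 3,
                               samples_per_stage = rep(150L, n_stages),
                               n_lncrna = 280, n_mrna = 300, n_icp = 10,
                               n_planted_specific = 20, planted_r = 0.8,
                               n_planted_uniform = 20, uniform_r = 0.6,
                               n_null_pairs = 200,
                               stage_shift = 0.5,
                               noise_sd = 0.5,
                               n_decoy_edges = 100, n_decoy_pairs = 30,
                               n_cell_types = 8, n_planted_cell_assoc = 6,
                               spatial = list(),
                               survival = list(),
                               seed = 1L) {
  spatial_def <- list(grid_side = 30L, n_cooccur = 5L, n_exclusive = 5L,
                      n_background_genes = 20L, background_rate = 0.05,
                      region_rate = 0.9, lambda = 2,
                      n_cell_types = 3L, markers_per_type = 5L)
  survival_def <- list(baseline_hazard = 1 / 1000, effect = 1,
                       censor_rate = 1 / 2000)
  spatial <- utils::modifyList(spatial_def, spatial)
  survival <- utils::modifyList(survival_def, survival)
  cfg <- list(n_stages = as.integer(n_stages),
              samples_per_stage = as.integer(samples_per_stage),
              n_lncrna = as.integer(n_lncrna), n_mrna = as.integer(n_mrna),
              n_icp = as.integer(n_icp),
              n_planted_specific = as.integer(n_planted_specific),
              planted_r = planted_r,
              n_planted_uniform = as.integer(n_planted_uniform),
              uniform_r = uniform_r,
              n_null_pairs = as.integer(n_null_pairs),
              stage_shift = stage_shift, noise_sd = noise_sd,
              n_decoy_edges = as.integer(n_decoy_edges),
              n_decoy_pairs = as.integer(n_decoy_pairs),
              n_cell_types = as.integer(n_cell_types),
              n_planted_cell_assoc = as.integer(n_planted_cell_assoc),
              spatial = spatial, survival = survival,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "synergy_sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_stages < 2) stop("need at least 2 stages", call. = FALSE)
  if (length(cfg$samples_per_stage) != cfg$n_stages ||
      any(cfg$samples_per_stage < 1)) {
    stop("`samples_per_stage` must give a positive size for every stage",
         call. = FALSE)
  }
  if (cfg$planted_r <= 0 || cfg$planted_r >= 1 ||
      cfg$uniform_r <= 0 || cfg$uniform_r >= 1) {
    stop("`planted_r` and `uniform_r` must lie in (0, 1)", call. = FALSE)
  }
  counts <- c(cfg$n_lncrna, cfg$n_mrna, cfg$n_icp, cfg$n_planted_specific,
              cfg$n_planted_uniform, cfg$n_null_pairs, cfg$n_decoy_edges,
              cfg$n_decoy_pairs, cfg$n_cell_types, cfg$n_planted_cell_assoc)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (cfg$n_icp < 1) stop("at least one ICP gene is required", call. = FALSE)
  n_pairs <- n_catalog_pairs(cfg)
  if (cfg$n_lncrna < n_pairs + cfg$n_decoy_pairs) {
    stop("planted pair counts exceed available lncRNAs", call. = FALSE)
  }
  if (cfg$n_mrna < n_pairs + cfg$n_decoy_pairs + cfg$n_icp) {
    stop("planted pair counts exceed available mRNAs", call. = FALSE)
  }
  if (cfg$n_planted_cell_assoc > cfg$n_cell_types ||
      cfg$n_planted_cell_assoc > n_pairs) {
    stop("more planted cell associations than cell types or pairs",
         call. = FALSE)
  }
  if (cfg$spatial$grid_side < 4) stop("spatial grid too small for planted regions",
                                      call. = FALSE)
  invisible(cfg)
}

n_catalog_pairs <- function(cfg) {
  cfg$n_planted_specific + cfg$n_planted_uniform + cfg$n_null_pairs
}

lnc_ids <- function(cfg) sprintf("LNC%04d", seq_len(cfg$n_lncrna))
mrna_ids <- function(cfg) sprintf("MRNA%04d", seq_len(cfg$n_mrna))
icp_ids <- function(cfg) {
  sprintf("MRNA%04d", seq(cfg$n_mrna - cfg$n_icp + 1L, cfg$n_mrna))
}

# one RNG stream per generator, at a fixed offset from the master seed
stream_seed <- function(cfg, offset) (cfg$seed + offset) %% 2147483647L

#' Pair-level ground truth of a simulated cohort
#'
#' @param cfg A [synergy_sim_config()].
#' @return Tibble with `lncrna`, `mrna`, `planted_class`
#'   (specific/uniform/null), `active_stage` (NA unless specific), `true_r`.
#' @keywords internal
pair_truth <- function(cfg) {
  n_pairs <- n_catalog_pairs(cfg)
  if (n_pairs == 0) {
    return(tibble::tibble(lncrna = character(), mrna = character(),
                          planted_class = character(),
                          active_stage = integer(), true_r = double()))
  }
  cls <- rep(c("specific", "uniform", "null"),
             c(cfg$n_planted_specific, cfg$n_planted_uniform, cfg$n_null_pairs))
  active <- rep(NA_integer_, n_pairs)
  if (cfg$n_planted_specific > 0) {
    # round-robin over stages so every stage hosts planted pairs
    active[cls == "specific"] <-
      (seq_len(cfg$n_planted_specific) - 1L) %% cfg$n_stages + 1L
  }
  tibble::tibble(
    lncrna = lnc_ids(cfg)[seq_len(n_pairs)],
    mrna = mrna_ids(cfg)[seq_len(n_pairs)],
    planted_class = cls,
    active_stage = active,
    true_r = dplyr::case_when(cls == "specific" ~ cfg$planted_r,
                              cls == "uniform" ~ cfg$uniform_r,
                              TRUE ~ 0)
  )
}

#' Simulate a stage-labelled expression cohort with planted pair structure
#'
#' Gene marginals are standard normal within each stage. A planted specific
#' pair's mRNA is, within the pair's active stage only, a Cholesky mix
#' `r * x + sqrt(1 - r^2) * z` of the lncRNA values `x` and fresh noise `z`,
#' giving exactly the target Pearson correlation in expectation and
#' independence elsewhere; uniform pairs are mixed in every stage. Each
#' catalogued pair's lncRNA additionally receives a deterministic per-stage
#' mean offset (`stage_shift` SD per stage step, centred) so that pair genes
#' are stage-differential.
#'
#' @param cfg A [synergy_sim_config()].
#' @return List with `expr` (a [stage_expression()]) and `truth`
#'   (the [pair_truth()] tibble).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "synergy_sim_config"))
  truth <- pair_truth(cfg)
  stages <- rep(seq_len(cfg$n_stages), cfg$samples_per_stage)
  n <- length(stages)
  genes <- c(lnc_ids(cfg), mrna_ids(cfg))
  withr::with_seed(stream_seed(cfg, 101L), {
    values <- matrix(stats::rnorm(length(genes) * n), nrow = length(genes),
                     dimnames = list(genes, sprintf("S%04d", seq_len(n))))
    for (i in seq_len(nrow(truth))) {
      if (truth$planted_class[i] == "null") next
      r <- truth$true_r[i]
      in_stage <- if (truth$planted_class[i] == "specific") {
        stages == truth$active_stage[i]
      } else {
        rep(TRUE, n)
      }
      x <- values[truth$lncrna[i], in_stage]
      values[truth$mrna[i], in_stage] <-
        r * x + sqrt(1 - r^2) * stats::rnorm(sum(in_stage))
    }
    if (cfg$stage_shift != 0 && nrow(truth) > 0) {
      shift <- (stages - (cfg$n_stages + 1) / 2) * cfg$stage_shift
      values[truth$lncrna, ] <-
        values[truth$lncrna, , drop = FALSE] +
        matrix(shift, nrow(truth), n, byrow = TRUE)
    }
  })
  gene_class <- tibble::tibble(
    gene = genes,
    class = rep(c("lncRNA", "mRNA"), c(cfg$n_lncrna, cfg$n_mrna)),
    is_icp = genes %in% icp_ids(cfg)
  )
  sample_stage <- tibble::tibble(sample = colnames(values), stage = stages)
  list(expr = stage_expression(values, sample_stage, gene_class),
       truth = truth)
}

#' Simulate the PPI network, interaction catalogue and ICP set
#'
#' Every catalogued pair's mRNA receives a PPI edge to an ICP gene
#' (round-robin), guaranteeing it lies in the ICP first-neighbourhood; decoy
#' edges are added among other mRNAs, and decoy interaction pairs use mRNAs
#' kept out of every ICP neighbourhood so they must be filtered downstream.
#'
#' @param cfg A [synergy_sim_config()].
#' @param decoys Set `FALSE` to omit decoy edges and decoy pairs.
#' @return List with `ppi` (tibble `gene_a`, `gene_b`), `catalog`
#'   (tibble `lncrna`, `mrna`, duplicate-free) and `icps` (character).
#' @export
simulate_network <- function(cfg, decoys = TRUE) {
  stopifnot(inherits(cfg, "synergy_sim_config"))
  truth <- pair_truth(cfg)
  icps <- icp_ids(cfg)
  n_pairs <- nrow(truth)
  anchor <- tibble::tibble(
    gene_a = truth$mrna,
    gene_b = icps[(seq_len(n_pairs) - 1L) %% cfg$n_icp + 1L]
  )
  catalog <- truth[, c("lncrna", "mrna")]
  if (decoys && cfg$n_decoy_pairs > 0) {
    decoy_lnc <- lnc_ids(cfg)[n_pairs + seq_len(cfg$n_decoy_pairs)]
    decoy_mrna <- mrna_ids(cfg)[n_pairs + seq_len(cfg$n_decoy_pairs)]
    catalog <- dplyr::bind_rows(catalog,
                                tibble::tibble(lncrna = decoy_lnc,
                                               mrna = decoy_mrna))
  } else {
    decoy_mrna <- character()
  }
  ppi <- anchor
  if (decoys && cfg$n_decoy_edges > 0) {
    # decoy edges stay clear of decoy-pair mRNAs so those remain unanchored
    pool <- setdiff(mrna_ids(cfg), c(decoy_mrna, icps))
    ppi <- withr::with_seed(stream_seed(cfg, 202L), {
      ea <- sample(pool, cfg$n_decoy_edges, replace = TRUE)
      eb <- sample(pool, cfg$n_decoy_edges, replace = TRUE)
      dplyr::bind_rows(anchor, tibble::tibble(gene_a = ea, gene_b = eb))
    })
    ppi <- dplyr::filter(ppi, .data$gene_a != .data$gene_b)
  }
  ppi <- dplyr::distinct(
    dplyr::mutate(ppi,
                  lo = pmin(.data$gene_a, .data$gene_b),
                  hi = pmax(.data$gene_a, .data$gene_b)),
    .data$lo, .data$hi
  )
  list(ppi = tibble::tibble(gene_a = ppi$lo, gene_b = ppi$hi),
       catalog = dplyr::distinct(catalog), icps = icps)
}

#' Simulate cell-type enrichment scores with planted gene associations
#'
#' Emulates the per-sample cell-type enrichment matrix an external scorer
#' (e.g. xCell) would produce. For the first `n_planted_cell_assoc`
#' catalogued pair lncRNAs, the matching cell type's score is a signed linear
#' function of the gene's expression plus Gaussian noise (`noise_sd`),
#' alternating positive and negative signs; all other cell types are
#' independent standard normal.
#'
#' @param cfg A [synergy_sim_config()].
#' @param expr The [stage_expression()] from [simulate_expression()].
#' @return List with `scores` (cell types x samples matrix) and `truth`
#'   (tibble `gene`, `cell_type`, `direction`).
#' @export
simulate_cell_scores <- function(cfg, expr) {
  stopifnot(inherits(cfg, "synergy_sim_config"), inherits(expr, "stage_expr"))
  base_names <- c("CD8_T", "CD4_Tcm", "NK", "B_cell", "M1_macrophage",
                  "Treg", "Dendritic", "Fibroblast")
  cell_types <- if (cfg$n_cell_types <= length(base_names)) {
    base_names[seq_len(cfg$n_cell_types)]
  } else {
    c(base_names, sprintf("CellType%02d", seq_len(cfg$n_cell_types - length(base_names))))
  }
  n <- ncol(expr$values)
  truth <- pair_truth(cfg)
  k <- cfg$n_planted_cell_assoc
  assoc <- tibble::tibble(
    gene = truth$lncrna[seq_len(k)],
    cell_type = cell_types[seq_len(k)],
    direction = rep_len(c(1, -1), k)
  )
  scores <- withr::with_seed(stream_seed(cfg, 303L), {
    m <- matrix(stats::rnorm(cfg$n_cell_types * n), cfg$n_cell_types,
                dimnames = list(cell_types, colnames(expr$values)))
    for (i in seq_len(nrow(assoc))) {
      g <- expr$values[assoc$gene[i], ]
      m[assoc$cell_type[i], ] <-
        assoc$direction[i] * g + cfg$noise_sd * stats::rnorm(n)
    }
    m
  })
  list(scores = scores, truth = assoc)
}

#' Simulate a spatial spot sample with planted pair relationships
#'
#' Spots live on a `grid_side` x `grid_side` integer grid. Planted
#' co-occurring pairs share presence in a common horizontal band; planted
#' exclusive pairs occupy complementary grid halves; background genes are
#' sparse Bernoulli presence everywhere. Positive counts are
#' `1 + Poisson(lambda)`. Marker genes of each simulated cell type are
#' enriched in that cell type's own band.
#'
#' @param cfg A [synergy_sim_config()].
#' @return List with `counts` (spots x genes integer matrix), `coords`
#'   (tibble `spot`, `x`, `y`), `truth` (tibble `gene1`, `gene2`,
#'   `relation`) and `markers` (tibble `cell_type`, `gene`).
#' @export
simulate_spatial <- function(cfg) {
  stopifnot(inherits(cfg, "synergy_sim_config"))
  sp <- cfg$spatial
  L <- sp$grid_side
  coords <- tibble::tibble(spot = sprintf("SP%04d", seq_len(L * L)),
                           x = rep(seq_len(L), times = L),
                           y = rep(seq_len(L), each = L))
  half <- floor(L / 2)
  withr::with_seed(stream_seed(cfg, 404L), {
    draw_presence <- function(region) {
      p <- ifelse(region, sp$region_rate, sp$background_rate)
      stats::rbinom(L * L, 1L, p)
    }
    to_counts <- function(pres) pres * (1L + stats::rpois(L * L, sp$lambda))
    genes <- list(); truth <- list()
    for (i in seq_len(sp$n_cooccur)) {
      y0 <- sample.int(L - half + 1L, 1L)
      band <- coords$y >= y0 & coords$y < y0 + half
      ga <- sprintf("COOC%02d_A", i); gb <- sprintf("COOC%02d_B", i)
      genes[[ga]] <- to_counts(draw_presence(band))
      genes[[gb]] <- to_counts(draw_presence(band))
      truth[[length(truth) + 1L]] <-
        tibble::tibble(gene1 = ga, gene2 = gb, relation = "cooccurrence")
    }
    for (i in seq_len(sp$n_exclusive)) {
      flip <- stats::runif(1) < 0.5
      left <- if (flip) coords$x <= half else coords$x > half
      ga <- sprintf("EXCL%02d_A", i); gb <- sprintf("EXCL%02d_B", i)
      genes[[ga]] <- to_counts(draw_presence(left))
      genes[[gb]] <- to_counts(draw_presence(!left))
      truth[[length(truth) + 1L]] <-
        tibble::tibble(gene1 = ga, gene2 = gb, relation = "exclusivity")
    }
    markers <- list()
    for (j in seq_len(sp$n_cell_types)) {
      y0 <- ((j - 1L) * half) %% L + 1L
      band <- coords$y >= y0 & coords$y < y0 + half
      for (k in seq_len(sp$markers_per_type)) {
        g <- sprintf("CT%02d_MARK%02d", j, k)
        genes[[g]] <- to_counts(draw_presence(band))
        markers[[length(markers) + 1L]] <-
          tibble::tibble(cell_type = sprintf("SpatialCT%02d", j), gene = g)
      }
    }
    for (i in seq_len(sp$n_background_genes)) {
      g <- sprintf("BG%03d", i)
      genes[[g]] <- to_counts(stats::rbinom(L * L, 1L, sp$background_rate))
    }
    counts <- do.call(cbind, genes)
    rownames(counts) <- coords$spot
  })
  list(counts = counts, coords = coords,
       truth = dplyr::bind_rows(truth),
       markers = dplyr::bind_rows(markers))
}

#' Simulate survival times with a planted signature effect
#'
#' Event times are exponential with per-sample hazard
#' `baseline_hazard * exp(effect * score)`; censoring is independent
#' exponential at `censor_rate`. Times are in days.
#'
#' @param cfg A [synergy_sim_config()].
#' @param scores Named numeric vector of per-sample signature scores.
#' @return Tibble with `sample`, `time` (days) and `event` (0 censored,
#'   1 death).
#' @export
simulate_survival <- function(cfg, scores) {
  stopifnot(inherits(cfg, "synergy_sim_config"), !is.null(names(scores)))
  sv <- cfg$survival
  withr::with_seed(stream_seed(cfg, 505L), {
    rate <- sv$baseline_hazard * exp(sv$effect * as.numeric(scores))
    t_event <- stats::rexp(length(scores), rate)
    t_cens <- stats::rexp(length(scores), sv$censor_rate)
    tibble::tibble(sample = names(scores),
                   time = pmin(t_event, t_cens),
                   event = as.integer(t_event <= t_cens))
  })
}

#' Simulate a complete synthetic study
#'
#' Runs every generator and derives the survival input from a planted
#' signature: the standardised mean expression of the lncRNAs belonging to
#' specific pairs active in the final stage.
#'
#' @param cfg A [synergy_sim_config()].
#' @return List with `config`, `expr`, `truth`, `ppi`, `catalog`, `icps`,
#'   `cell_scores`, `cell_truth`, `spatial`, `signature_genes`,
#'   `signature_score` and `survival`.
#' @export
simulate_study <- function(cfg) {
  ex <- simulate_expression(cfg)
  net <- simulate_network(cfg)
  cells <- simulate_cell_scores(cfg, ex$expr)
  spat <- simulate_spatial(cfg)
  last <- cfg$n_stages
  sig_genes <- ex$truth$lncrna[ex$truth$planted_class == "specific" &
                                 !is.na(ex$truth$active_stage) &
                                 ex$truth$active_stage == last]
  score <- if (length(sig_genes)) {
    as.numeric(scale(colMeans(ex$expr$values[sig_genes, , drop = FALSE])))
  } else {
    rep(0, ncol(ex$expr$values))
  }
  names(score) <- colnames(ex$expr$values)
  surv <- simulate_survival(cfg, score)
  list(config = cfg, expr = ex$expr, truth = ex$truth,
       ppi = net$ppi, catalog = net$catalog, icps = net$icps,
       cell_scores = cells$scores, cell_truth = cells$truth,
       spatial = spat, signature_genes = sig_genes,
       signature_score = score, survival = surv)
}
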