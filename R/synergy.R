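# Per-stage Pearson sufficient statistics and the ssLIss kernel.
#
# All permutation work funnels through sums computed with rowsum() on the
# columns (x, y, x^2, y^2, xy), so a trial costs one O(n) pass.

pair_moment_matrix <- function(x, y) cbind(x, y, x * x, y * y, x * y)

# r and two-sided p (t reference, n-2 df) per stage from group sums
stage_r_p <- function(S, n_j) {
  sx <- S[, 1]; sy <- S[, 2]
  vx <- S[, 3] - sx^2 / n_j
  vy <- S[, 4] - sy^2 / n_j
  cv <- S[, 5] - sx * sy / n_j
  r <- rep(0, length(n_j))
  p <- rep(1, length(n_j))
  ok <- vx > 0 & vy > 0 & n_j > 2
  r[ok] <- pmax(-1, pmin(1, cv[ok] / sqrt(vx[ok] * vy[ok])))
  exact <- ok & abs(r) >= 1
  p[exact] <- 0
  tok <- ok & !exact
  tt <- r[tok] * sqrt((n_j[tok] - 2) / (1 - r[tok]^2))
  p[tok] <- 2 * stats::pt(-abs(tt), n_j[tok] - 2)
  list(r = r, p = p, degenerate = !(vx > 0 & vy > 0))
}

ssliss_from_sums <- function(S, n_j, sig_alpha) {
  rp <- stage_r_p(S, n_j)
  adj <- ifelse(rp$p < sig_alpha, rp$r, 0)
  ssliss(adj)
}

#' Stage-specificity synergy score (ssLIss)
#'
#' Scores how concentrated a pair's significant co-expression is in a single
#' stage. Given the vector of significance-adjusted per-stage Pearson
#' correlations (the correlation where its p < 0.05, else 0), the score is
#'
#' \deqn{\mathrm{ssLIss} = \frac{\sum_j \left(1 - |a_j| / \max_j |a_j|\right)}
#'   {N - 1} \cdot \frac{\max_j |a_j|}{0.75}}
#'
#' where \eqn{a_j} is the adjusted correlation in stage \eqn{j} and \eqn{N}
#' the number of stages. A pair significant in exactly one stage scores
#' `max|a|/0.75`; a uniformly correlated pair scores 0. When every adjusted
#' correlation is 0 the formula is 0/0 and the score is defined as 0 (no
#' significant correlation anywhere means no synergy). The `max|a|/0.75`
#' factor is kept as defined, so scores may exceed 1 when `max|a| > 0.75`;
#' the range is `[0, 4/3]`.
#'
#' @param adjusted_r Numeric vector of adjusted per-stage correlations,
#'   one per stage (length >= 2).
#' @return The score, a single number in `[0, 4/3]`.
#' @examples
#' ssliss(c(0.75, 0, 0, 0))  # 1
#' ssliss(c(0.6, 0.6, 0.6))  # 0
#' ssliss(c(0.75, 0.3, 0))   # 0.8
#' @export
ssliss <- function(adjusted_r) {
  n <- length(adjusted_r)
  if (n < 2) stop("ssLIss needs at least 2 stages (denominator N - 1)",
                  call. = FALSE)
  a <- abs(adjusted_r)
  m <- max(a)
  if (m == 0) return(0)
  sum(1 - a / m) / (n - 1) * (m / 0.75)
}

#' Per-stage adjusted Pearson correlations for candidate pairs
#'
#' For each pair and each stage, the Pearson correlation between the two
#' genes over that stage's samples, its two-sided p-value (t reference,
#' n - 2 df) and the significance-adjusted value (`r` when `p < sig_alpha`,
#' else 0). A gene with zero variance within a stage yields r = 0, p = 1
#' with a warning.
#'
#' @param expr A [stage_expression()]; every stage should have >= 3 samples.
#' @param pairs Data frame with columns `lncrna`, `mrna`.
#' @param sig_alpha Per-stage significance threshold for the adjustment
#'   (default 0.05).
#' @return Tibble with `lncrna`, `mrna`, `stage`, `n`, `r`, `p`,
#'   `adjusted_r`, ordered by pair then stage.
#' @export
stage_correlations <- function(expr, pairs, sig_alpha = 0.05) {
  stopifnot(inherits(expr, "stage_expr"))
  pairs <- tibble::as_tibble(pairs)[, c("lncrna", "mrna")]
  stages <- stage_vector(expr)
  lev <- sort(unique(stages))
  stg <- match(stages, lev)
  n_j <- tabulate(stg, length(lev))
  out <- purrr::pmap(pairs, function(lncrna, mrna) {
    M <- pair_moment_matrix(expr$values[lncrna, ], expr$values[mrna, ])
    S <- rowsum(M, stg)
    rp <- stage_r_p(S, n_j)
    if (any(rp$degenerate)) {
      warning("zero-variance gene in pair ", lncrna, "-", mrna,
              " within stage(s) ", paste(lev[rp$degenerate], collapse = ","),
              "; correlation set to 0", call. = FALSE)
    }
    tibble::tibble(lncrna = lncrna, mrna = mrna, stage = lev, n = n_j,
                   r = rp$r, p = rp$p,
                   adjusted_r = ifelse(rp$p < sig_alpha, rp$r, 0))
  })
  dplyr::bind_rows(out)
}

#' Specific stage of a correlation profile
#'
#' The stage attaining the maximum absolute adjusted correlation; ties are
#' broken deterministically by the earliest stage. When every adjusted
#' correlation is 0 no stage is assigned (`NA`).
#'
#' @param adjusted_r Numeric vector of adjusted per-stage correlations.
#' @param stages Stage ids, parallel to `adjusted_r` and in increasing
#'   order (default `seq_along(adjusted_r)`).
#' @return A single stage id, or `NA` when all adjusted correlations are 0.
#' @examples
#' assign_specific_stage(c(0.2, -0.9, 0.4))  # 2
#' assign_specific_stage(c(0.8, 0.8))        # 1 (earliest-stage tie-break)
#' @export
assign_specific_stage <- function(adjusted_r, stages = seq_along(adjusted_r)) {
  stopifnot(length(adjusted_r) == length(stages))
  a <- abs(adjusted_r)
  if (max(a) == 0) return(stages[NA_integer_])
  stages[which.max(a)]
}

# deterministic per-pair RNG seed: polynomial string hash folded with the
# master seed, kept below 2^31 so set.seed() accepts it anywhere
pair_seed <- function(seed, lncrna, mrna) {
  codes <- utf8ToInt(paste(lncrna, mrna, sep = "\r"))
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

#' Permutation p-value for a pair's ssLIss
#'
#' Random perturbation trials: in each trial the sample-to-stage labels are
#' shuffled across all samples (stage sizes preserved) and the full adjusted
#' correlation + ssLIss computation is repeated, targeting the null of no
#' stage-specific structure while preserving each gene's marginal
#' distribution. The empirical p uses the add-one convention
#' `(1 + #\{null >= observed\}) / (B + 1)`, so it is never exactly zero.
#'
#' @param expr A [stage_expression()].
#' @param lncrna,mrna Gene ids of the pair.
#' @param B Number of trials (default 1000).
#' @param sig_alpha Per-stage adjustment threshold (default 0.05).
#' @param seed RNG seed for the trials.
#' @return List with `observed` (the pair's ssLIss), `perm_p` and
#'   `null_scores` (length `B`).
#' @export
permutation_pvalue <- function(expr, lncrna, mrna, B = 1000,
                               sig_alpha = 0.05, seed = 1L) {
  stopifnot(inherits(expr, "stage_expr"), B >= 1)
  stages <- stage_vector(expr)
  lev <- sort(unique(stages))
  stg <- match(stages, lev)
  n_j <- tabulate(stg, length(lev))
  M <- pair_moment_matrix(expr$values[lncrna, ], expr$values[mrna, ])
  observed <- ssliss_from_sums(rowsum(M, stg), n_j, sig_alpha)
  n <- nrow(M)
  null_scores <- withr::with_seed(as.integer(seed) %% 2147483647L, {
    vapply(seq_len(B), function(b) {
      ssliss_from_sums(rowsum(M[sample.int(n), , drop = FALSE], stg),
                       n_j, sig_alpha)
    }, numeric(1))
  })
  list(observed = observed,
       perm_p = (1 + sum(null_scores >= observed)) / (B + 1),
       null_scores = null_scores)
}

#' Score all candidate pairs for stage-specific synergy
#'
#' Computes, for every candidate pair, the per-stage adjusted Pearson
#' correlations, the ssLIss score, its permutation p-value and the specific
#' stage. A pair is called significant iff `perm_p < perm_alpha` and at
#' least one stage has a nonzero adjusted correlation. Each pair draws its
#' permutations from a substream keyed by `(seed, pair id)`, so results do
#' not depend on the order of the candidate table.
#'
#' @param expr A stage-filtered [stage_expression()].
#' @param candidates Data frame with columns `lncrna`, `mrna`
#'   (e.g. from [build_candidates()]).
#' @param B Permutation trials per pair (default 1000).
#' @param sig_alpha Per-stage correlation significance threshold (0.05).
#' @param perm_alpha Empirical p-value threshold for significance (0.05).
#' @param seed Master RNG seed.
#' @return A `synergy_scan` object: list with `results` (one row per pair:
#'   `lncrna`, `mrna`, `ssliss`, `max_abs_adjusted`, `n_stages`, `perm_p`,
#'   `specific_stage`, `significant`), `profiles` (the long
#'   [stage_correlations()] table) and `params`. Use [tidy()] / [glance()] /
#'   [autoplot()] on it.
#' @export
score_synergy <- function(expr, candidates, B = 1000, sig_alpha = 0.05,
                          perm_alpha = 0.05, seed = 1L) {
  stopifnot(inherits(expr, "stage_expr"), B >= 1,
            perm_alpha > 0, perm_alpha < 1)
  candidates <- tibble::as_tibble(candidates)
  params <- list(B = B, sig_alpha = sig_alpha, perm_alpha = perm_alpha,
                 seed = as.integer(seed))
  if (nrow(candidates) == 0) {
    empty <- tibble::tibble(lncrna = character(), mrna = character(),
                            ssliss = double(), max_abs_adjusted = double(),
                            n_stages = integer(), perm_p = double(),
                            specific_stage = integer(),
                            significant = logical())
    return(structure(list(results = empty,
                          profiles = stage_correlations(expr, candidates),
                          params = params),
                     class = "synergy_scan"))
  }
  profiles <- stage_correlations(expr, candidates, sig_alpha)
  stages <- stage_vector(expr)
  lev <- sort(unique(stages))
  stg <- match(stages, lev)
  n_j <- tabulate(stg, length(lev))
  n <- length(stg)
  res <- purrr::pmap(candidates[, c("lncrna", "mrna")],
                     function(lncrna, mrna) {
    prof <- profiles[profiles$lncrna == lncrna & profiles$mrna == mrna, ]
    adj <- prof$adjusted_r
    obs <- ssliss(adj)
    M <- pair_moment_matrix(expr$values[lncrna, ], expr$values[mrna, ])
    null_scores <- withr::with_seed(pair_seed(seed, lncrna, mrna), {
      vapply(seq_len(B), function(b) {
        ssliss_from_sums(rowsum(M[sample.int(n), , drop = FALSE], stg),
                         n_j, sig_alpha)
      }, numeric(1))
    })
    perm_p <- (1 + sum(null_scores >= obs)) / (B + 1)
    max_abs <- max(abs(adj))
    tibble::tibble(lncrna = lncrna, mrna = mrna, ssliss = obs,
                   max_abs_adjusted = max_abs,
                   n_stages = length(lev), perm_p = perm_p,
                   specific_stage = assign_specific_stage(adj, lev),
                   significant = perm_p < perm_alpha && max_abs > 0)
  })
  structure(list(results = dplyr::bind_rows(res), profiles = profiles,
                 params = params),
            class = "synergy_scan")
}

#' @export
print.synergy_scan <- function(x, ...) {
  cat("<synergy_scan> ", nrow(x$results), " pairs, ",
      sum(x$results$significant), " significant (B = ", x$params$B,
      ", alpha = ", x$params$perm_alpha, ")\n", sep = "")
  print(x$results, n = 5)
  invisible(x)
}
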