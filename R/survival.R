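#' Up/down differential gene sets for the final stage
#'
#' Per gene, a two-sided Wilcoxon rank-sum test of the target stage's
#' samples against all other stages; genes with `p < alpha` are split by
#' the sign of (median in target stage - median elsewhere) into up- and
#' down-regulated sets. Genes identical across groups are excluded.
#'
#' @param expr A [stage_expression()].
#' @param genes Gene universe to test (e.g. the genes of pairs whose
#'   specific stage is the target stage); must be non-empty.
#' @param target_stage The stage contrasted against the rest (default the
#'   highest stage present).
#' @param alpha Significance threshold (default 0.05).
#' @return List with character vectors `up` and `down`.
#' @export
stage_differential_sets <- function(expr, genes,
                                    target_stage = max(stage_vector(expr)),
                                    alpha = 0.05) {
  stopifnot(inherits(expr, "stage_expr"))
  genes <- intersect(genes, rownames(expr$values))
  if (!length(genes)) stop("empty gene universe", call. = FALSE)
  stages <- stage_vector(expr)
  in_target <- stages == target_stage
  if (!any(in_target) || all(in_target)) {
    stop("both the target stage and the rest must be non-empty", call. = FALSE)
  }
  up <- character(); down <- character()
  for (g in genes) {
    x <- expr$values[g, in_target]
    y <- expr$values[g, !in_target]
    if (length(unique(c(x, y))) == 1) next
    p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    if (is.na(p) || p >= alpha) next
    delta <- stats::median(x) - stats::median(y)
    if (delta > 0) up <- c(up, g) else if (delta < 0) down <- c(down, g)
  }
  list(up = up, down = down)
}

#' PLAGE single-sample gene-set scores
#'
#' Pathway-level analysis of gene expression: each set gene's expression is
#' z-scored across samples, and the first right singular vector of the
#' resulting genes x samples matrix is the per-sample score (unit Euclidean
#' norm). The SVD sign is arbitrary, so the vector is oriented to correlate
#' non-negatively with the mean z-scored expression of the set, making a
#' high score mean high overall set expression. Scores are invariant to
#' per-gene affine rescaling of the raw expression.
#'
#' @param expr A [stage_expression()] or a genes x samples numeric matrix.
#' @param gene_set Character vector of set members (>= 1 present in the
#'   matrix after dropping zero-variance genes).
#' @return Named numeric vector of per-sample scores, unit norm.
#' @export
plage_scores <- function(expr, gene_set) {
  values <- if (inherits(expr, "stage_expr")) expr$values else expr
  stopifnot(is.matrix(values), ncol(values) >= 2)
  gene_set <- unique(gene_set)
  present <- intersect(gene_set, rownames(values))
  if (!length(present)) stop("no gene-set member present in the matrix",
                             call. = FALSE)
  sub <- values[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance gene(s) dropped from the set: ",
            paste(present[sds == 0], collapse = ", "), call. = FALSE)
    sub <- sub[sds > 0, , drop = FALSE]
    if (!nrow(sub)) stop("all gene-set members have zero variance",
                         call. = FALSE)
  }
  z <- t(scale(t(sub)))
  sv <- svd(z, nu = 0, nv = 1)
  score <- sv$v[, 1]
  ref <- colMeans(z)
  if (stats::sd(ref) > 0 && stats::cor(score, ref) < 0) score <- -score
  names(score) <- colnames(values)
  score
}

#' Split samples at the median score
#'
#' Samples scoring strictly above the median go to `high`; those at or
#' below it (including exact ties with the median) go to `low`. With an odd
#' sample count the median sample itself therefore lands in `low`.
#'
#' @param scores Named numeric vector of per-sample scores.
#' @return Named factor with levels `low`, `high`.
#' @examples
#' median_split(c(a = 1, b = 2, c = 3, d = 4))  # a,b low; c,d high
#' @export
median_split <- function(scores) {
  med <- stats::median(scores)
  factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (1 df) comparing survival between two
#' groups: the observed-minus-expected event sum over distinct event times
#' with hypergeometric variance, via [survival::survdiff()]. Both groups
#' must be non-empty. With no events at all the statistic is 0 and p = 1
#' (returned with a warning). The statistic is symmetric in the group
#' labels.
#'
#' @param surv Data frame with columns `sample`, `time` (days, >= 0) and
#'   `event` (0 censored / 1 death).
#' @param groups Factor or character vector of two group labels, either
#'   named by sample or parallel to the rows of `surv`.
#' @return Tibble with `chi2`, `p`, `n_low`/`n_high`-style per-group sizes
#'   (`n_<level>`) and `n_events`.
#' @export
logrank_test <- function(surv, groups) {
  surv <- tibble::as_tibble(surv)
  stopifnot(all(c("time", "event") %in% names(surv)),
            all(surv$time >= 0), all(surv$event %in% c(0, 1)))
  if (!is.null(names(groups))) {
    stopifnot("sample" %in% names(surv))
    groups <- groups[surv$sample]
  }
  stopifnot(length(groups) == nrow(surv))
  g <- factor(groups)
  g <- droplevels(g)
  if (nlevels(g) != 2) {
    stop("log-rank comparison needs exactly two non-empty groups (got ",
         nlevels(g), ")", call. = FALSE)
  }
  sizes <- table(g)
  if (sum(surv$event) == 0) {
    warning("no events: log-rank statistic is 0 by definition", call. = FALSE)
    chi2 <- 0; p <- 1
  } else {
    sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ g)
    chi2 <- unname(sd$chisq)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  out <- tibble::tibble(chi2 = chi2, p = p, n_events = sum(surv$event))
  out[paste0("n_", levels(g))] <- as.list(as.integer(sizes))
  out
}

#' Score a gene signature and stratify survival
#'
#' End-to-end survival stratification for one gene set: PLAGE scores per
#' sample, median split into high/low groups, and a log-rank comparison of
#' the two groups.
#'
#' @param expr A [stage_expression()] or genes x samples matrix.
#' @param gene_set Character vector of signature genes.
#' @param surv Survival table (`sample`, `time`, `event`) covering the
#'   expression samples.
#' @param direction Label for the signature (e.g. `"up"` or `"down"`),
#'   carried through to the output.
#' @param set_id Identifier for the gene set.
#' @return A `signature_survival` object: list with `scores` (tibble
#'   `sample`, `score`, `group`), `logrank` (tibble from [logrank_test()]),
#'   `gene_set`, `direction`, `set_id`, and `surv`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
signature_survival <- function(expr, gene_set, surv, direction = "up",
                               set_id = "signature") {
  score <- plage_scores(expr, gene_set)
  surv <- tibble::as_tibble(surv)
  surv <- surv[surv$sample %in% names(score), ]
  score <- score[surv$sample]
  group <- median_split(score)
  lr <- logrank_test(surv, group)
  structure(
    list(scores = tibble::tibble(sample = names(score),
                                 score = unname(score),
                                 group = unname(group)),
         logrank = lr, gene_set = gene_set, direction = direction,
         set_id = set_id, surv = surv),
    class = "signature_survival"
  )
}

#' @export
print.signature_survival <- function(x, ...) {
  cat("<signature_survival> '", x$set_id, "' (", x$direction, "), ",
      length(x$gene_set), " genes, ", nrow(x$scores), " samples\n",
      "  log-rank chi2 = ", signif(x$logrank$chi2, 4),
      ", p = ", signif(x$logrank$p, 4), "\n", sep = "")
  invisible(x)
}
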