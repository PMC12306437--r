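#' Stage-wise Spearman association between genes and cell-type scores
#'
#' For every (gene, cell type, stage) combination, the tie-corrected
#' Spearman correlation between the gene's expression and the cell type's
#' per-sample enrichment score over that stage's samples, with a two-sided
#' p-value; only associations with `p < alpha` are retained. Scores are
#' consumed as produced by an external cell-type scorer (e.g. xCell) and
#' only their ranks matter, so any monotone transform of the scores leaves
#' the output unchanged.
#'
#' @param expr A [stage_expression()].
#' @param cell_scores Cell types x samples numeric matrix; column names
#'   must be a subset of the expression samples.
#' @param genes Gene ids to test (e.g. genes of significant synergy pairs).
#' @param alpha Retention threshold on the raw p-value (default 0.05).
#' @param cancer Optional cancer-type label copied into the output.
#' @return Tibble with `cancer`, `gene`, `cell_type`, `stage`, `n`, `rho`,
#'   `p`, `sign` (`"+"`/`"-"`). Cell types with a constant score within a
#'   stage are skipped with a warning.
#' @export
stage_spearman <- function(expr, cell_scores, genes, alpha = 0.05,
                           cancer = NA_character_) {
  stopifnot(inherits(expr, "stage_expr"), is.matrix(cell_scores))
  if (!all(colnames(cell_scores) %in% colnames(expr$values))) {
    stop("cell-score samples are not a subset of expression samples",
         call. = FALSE)
  }
  genes <- intersect(genes, rownames(expr$values))
  samples <- colnames(cell_scores)
  stage_of <- stage_vector(expr)[match(samples, colnames(expr$values))]
  out <- list()
  skipped <- character()
  for (st in sort(unique(stage_of))) {
    idx <- samples[stage_of == st]
    if (length(idx) < 4) next
    for (ct in rownames(cell_scores)) {
      sc <- cell_scores[ct, idx]
      if (length(unique(sc)) == 1) {
        skipped <- union(skipped, ct)
        next
      }
      for (g in genes) {
        gv <- expr$values[g, idx]
        if (length(unique(gv)) == 1) next
        ht <- suppressWarnings(
          stats::cor.test(gv, sc, method = "spearman", exact = FALSE)
        )
        if (is.na(ht$p.value) || ht$p.value >= alpha) next
        out[[length(out) + 1L]] <- tibble::tibble(
          cancer = cancer, gene = g, cell_type = ct, stage = st,
          n = length(idx), rho = unname(ht$estimate), p = ht$p.value,
          sign = if (ht$estimate > 0) "+" else "-"
        )
      }
    }
  }
  if (length(skipped)) {
    warning("constant score vector, cell type(s) skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  if (!length(out)) {
    return(tibble::tibble(cancer = character(), gene = character(),
                          cell_type = character(), stage = integer(),
                          n = integer(), rho = double(), p = double(),
                          sign = character()))
  }
  dplyr::bind_rows(out)
}

#' Two-group difference in cell-type enrichment scores
#'
#' Two-sided Wilcoxon rank-sum test per cell type between two sample groups
#' (e.g. early vs advanced stages, or metastatic vs non-metastatic).
#' Rank-based, so invariant to monotone transforms of the scores; two
#' groups with identical constant values yield p = 1.
#'
#' @param cell_scores Cell types x samples numeric matrix.
#' @param group_a,group_b Non-overlapping, non-empty character vectors of
#'   sample ids (must be score columns).
#' @return Tibble with `cell_type` and `p`.
#' @export
stage_difference_test <- function(cell_scores, group_a, group_b) {
  stopifnot(is.matrix(cell_scores), length(group_a) > 0, length(group_b) > 0)
  missing <- setdiff(c(group_a, group_b), colnames(cell_scores))
  if (length(missing)) {
    stop("samples absent from the score matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  p <- vapply(rownames(cell_scores), function(ct) {
    a <- cell_scores[ct, group_a]
    b <- cell_scores[ct, group_b]
    if (length(unique(c(a, b))) == 1) return(1)
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  }, numeric(1))
  tibble::tibble(cell_type = rownames(cell_scores), p = unname(p))
}

#' Count cancer-stage-cell processes per gene
#'
#' A gene participates in a cancer-stage-cell process when it is
#' significantly correlated with a cell type's enrichment score at a given
#' stage of a given cancer. Counts distinct (cancer, stage, cell type)
#' triples per gene; duplicate association rows collapse to one triple.
#'
#' @param associations Tibble of associations (from [stage_spearman()],
#'   possibly row-bound across cancers) with columns `gene`, `cancer`,
#'   `stage`, `cell_type`.
#' @return Tibble with `gene` and `n_processes`, sorted descending.
#' @export
cancer_stage_cell_processes <- function(associations) {
  tibble::as_tibble(associations) |>
    dplyr::distinct(.data$gene, .data$cancer, .data$stage, .data$cell_type) |>
    dplyr::count(.data$gene, name = "n_processes") |>
    dplyr::arrange(dplyr::desc(.data$n_processes), .data$gene)
}

#' Direction consistency of gene-cell associations across cancer stages
#'
#' For each (gene, cell type) relationship observed in at least `min_combos`
#' distinct cancer-stage combinations, counts the positive and negative
#' correlations and the consistency fraction `max(n+, n-) / (n+ + n-)`.
#' Relationships seen in fewer combinations are excluded.
#'
#' @param associations Association tibble with columns `gene`, `cell_type`,
#'   `cancer`, `stage`, `rho`.
#' @param min_combos Minimum cancer-stage combinations (default 10).
#' @return Tibble with `gene`, `cell_type`, `n_combos`, `n_positive`,
#'   `n_negative`, `consistency`.
#' @export
direction_consistency <- function(associations, min_combos = 10) {
  stopifnot(min_combos >= 1)
  tibble::as_tibble(associations) |>
    dplyr::distinct(.data$gene, .data$cell_type, .data$cancer, .data$stage,
                    .keep_all = TRUE) |>
    dplyr::group_by(.data$gene, .data$cell_type) |>
    dplyr::summarise(n_combos = dplyr::n(),
                     n_positive = sum(.data$rho > 0),
                     n_negative = sum(.data$rho < 0),
                     .groups = "drop") |>
    dplyr::filter(.data$n_combos >= min_combos) |>
    dplyr::mutate(consistency = pmax(.data$n_positive, .data$n_negative) /
                    (.data$n_positive + .data$n_negative))
}
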