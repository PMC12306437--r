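#' Classify cross-stage co-expression patterns
#'
#' Assigns each pair with at least one nonzero adjusted correlation one of
#' four patterns, from the sign pattern alone (magnitudes are irrelevant):
#' `stage_converted` when the nonzero signs include both + and -; otherwise
#' `early_specific` when every nonzero stage is early, `advanced_specific`
#' when every nonzero stage is advanced, and `stage_common` when they span
#' both. Early defaults to stages I-II and advanced to III-IV. The four
#' labels are mutually exclusive and exhaustive. Pairs whose adjusted
#' correlations are all zero receive no call and are dropped.
#'
#' @param scan A `synergy_scan` from [score_synergy()], or a long profile
#'   tibble with columns `lncrna`, `mrna`, `stage`, `adjusted_r`.
#' @param early_stages,advanced_stages Partition of the stage set
#'   (defaults `c(1, 2)` / `c(3, 4)`; surviving stages must fall in one of
#'   the two).
#' @param only_significant When `scan` is a `synergy_scan`, classify only
#'   pairs called significant (default `TRUE`).
#' @return Tibble with `lncrna`, `mrna`, `pattern`, `n_significant_stages`
#'   and `signs` (per-stage `-`/`0`/`+` string in stage order).
#' @export
classify_patterns <- function(scan, early_stages = c(1, 2),
                              advanced_stages = c(3, 4),
                              only_significant = TRUE) {
  if (inherits(scan, "synergy_scan")) {
    profiles <- scan$profiles
    if (only_significant) {
      keep <- scan$results[scan$results$significant, c("lncrna", "mrna")]
      profiles <- dplyr::semi_join(profiles, keep, by = c("lncrna", "mrna"))
    }
  } else {
    profiles <- tibble::as_tibble(scan)
  }
  if (length(intersect(early_stages, advanced_stages))) {
    stop("early and advanced stage sets must be disjoint", call. = FALSE)
  }
  uncovered <- setdiff(unique(profiles$stage), c(early_stages, advanced_stages))
  if (length(uncovered)) {
    stop("stage(s) ", paste(uncovered, collapse = ","),
         " fall in neither the early nor the advanced set", call. = FALSE)
  }
  profiles <- dplyr::arrange(profiles, .data$lncrna, .data$mrna, .data$stage)
  out <- profiles |>
    dplyr::group_by(.data$lncrna, .data$mrna) |>
    dplyr::summarise(
      pattern = classify_sign_pattern(.data$adjusted_r,
                                      .data$stage %in% early_stages),
      n_significant_stages = sum(.data$adjusted_r != 0),
      signs = paste(c("-", "0", "+")[sign(.data$adjusted_r) + 2],
                    collapse = ""),
      .groups = "drop"
    )
  dplyr::filter(out, !is.na(.data$pattern))
}

#' Classify a single pair's cross-stage pattern
#'
#' Single-profile version of [classify_patterns()]: applies the same rules
#' to one vector of per-stage adjusted correlations. A profile with no
#' nonzero adjusted correlation has no pattern and is an error.
#'
#' @param adjusted_r Numeric vector of adjusted per-stage correlations.
#' @param stages Stage ids parallel to `adjusted_r` (default
#'   `seq_along(adjusted_r)`).
#' @param early_stages,advanced_stages Disjoint partition of the stages.
#' @return One of `"early_specific"`, `"advanced_specific"`,
#'   `"stage_common"`, `"stage_converted"`.
#' @examples
#' classify_pattern(c(0.8, 0, 0, 0))     # early_specific
#' classify_pattern(c(0.5, 0, 0, 0.5))   # stage_common
#' classify_pattern(c(0, 0.4, 0, -0.6))  # stage_converted
#' @export
classify_pattern <- function(adjusted_r, stages = seq_along(adjusted_r),
                             early_stages = c(1, 2),
                             advanced_stages = c(3, 4)) {
  stopifnot(length(adjusted_r) == length(stages))
  if (length(intersect(early_stages, advanced_stages))) {
    stop("early and advanced stage sets must be disjoint", call. = FALSE)
  }
  if (length(setdiff(stages, c(early_stages, advanced_stages)))) {
    stop("every stage must fall in the early or the advanced set",
         call. = FALSE)
  }
  if (all(adjusted_r == 0)) {
    stop("no call: all adjusted correlations are zero", call. = FALSE)
  }
  classify_sign_pattern(adjusted_r, stages %in% early_stages)
}

classify_sign_pattern <- function(adjusted_r, is_early) {
  nz <- adjusted_r != 0
  if (!any(nz)) return(NA_character_)
  s <- sign(adjusted_r[nz])
  if (any(s > 0) && any(s < 0)) return("stage_converted")
  if (all(is_early[nz])) return("early_specific")
  if (all(!is_early[nz])) return("advanced_specific")
  "stage_common"
}

#' How many stages each pair co-expresses in
#'
#' Histogram of pairs by their number of stages with a nonzero adjusted
#' correlation. Counts are conserved: the histogram total equals the number
#' of input pairs.
#'
#' @param scan A `synergy_scan` or a profile tibble (see
#'   [classify_patterns()]).
#' @param only_significant Restrict to significant pairs when a
#'   `synergy_scan` is given (default `TRUE`).
#' @return Tibble with `n_significant_stages` and `n_pairs`.
#' @export
stage_multiplicity <- function(scan, only_significant = TRUE) {
  if (inherits(scan, "synergy_scan")) {
    profiles <- scan$profiles
    if (only_significant) {
      keep <- scan$results[scan$results$significant, c("lncrna", "mrna")]
      profiles <- dplyr::semi_join(profiles, keep, by = c("lncrna", "mrna"))
    }
  } else {
    profiles <- tibble::as_tibble(scan)
  }
  profiles |>
    dplyr::group_by(.data$lncrna, .data$mrna) |>
    dplyr::summarise(k = sum(.data$adjusted_r != 0), .groups = "drop") |>
    dplyr::count(.data$k, name = "n_pairs") |>
    dplyr::rename(n_significant_stages = "k")
}

#' Per-gene pattern participation counts
#'
#' For each gene (lncRNA or mRNA), how many of its pairs fall in each
#' co-expression pattern. Row sums equal the gene's pair count; genes are
#' sorted by total participation, descending.
#'
#' @param calls Output of [classify_patterns()].
#' @return Tibble with `gene`, one count column per pattern, and `total`.
#' @export
pattern_gene_summary <- function(calls) {
  calls <- tibble::as_tibble(calls)
  levels <- c("early_specific", "advanced_specific", "stage_common",
              "stage_converted")
  long <- dplyr::bind_rows(
    tibble::tibble(gene = calls$lncrna, pattern = calls$pattern),
    tibble::tibble(gene = calls$mrna, pattern = calls$pattern)
  )
  long$pattern <- factor(long$pattern, levels = levels)
  long |>
    dplyr::count(.data$gene, .data$pattern, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "pattern", values_from = "n",
                       values_fill = 0L) |>
    dplyr::mutate(total = rowSums(dplyr::across(dplyr::all_of(levels)))) |>
    dplyr::arrange(dplyr::desc(.data$total), .data$gene)
}
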