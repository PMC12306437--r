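#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a synergy scan into its per-pair result table
#'
#' @param x A `synergy_scan` from [score_synergy()].
#' @param ... Unused.
#' @return Tibble, one row per candidate pair.
#' @method tidy synergy_scan
#' @export
tidy.synergy_scan <- function(x, ...) x$results

#' One-row summary of a synergy scan
#'
#' @param x A `synergy_scan`.
#' @param ... Unused.
#' @return One-row tibble with pair counts and scan parameters.
#' @method glance synergy_scan
#' @export
glance.synergy_scan <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$results),
    n_significant = sum(x$results$significant),
    n_stages = if (nrow(x$results)) x$results$n_stages[1] else NA_integer_,
    B = x$params$B,
    sig_alpha = x$params$sig_alpha,
    perm_alpha = x$params$perm_alpha,
    seed = x$params$seed
  )
}

#' Per-sample table of a signature-survival stratification
#'
#' @param x A `signature_survival` from [signature_survival()].
#' @param ... Unused.
#' @return Tibble with `sample`, `score`, `group`, `time`, `event`.
#' @method tidy signature_survival
#' @export
tidy.signature_survival <- function(x, ...) {
  dplyr::left_join(x$scores, x$surv, by = "sample")
}

#' One-row summary of a signature-survival stratification
#'
#' @param x A `signature_survival`.
#' @param ... Unused.
#' @return One-row tibble with the set id, direction, sizes and the
#'   log-rank chi-square and p-value.
#' @method glance signature_survival
#' @export
glance.signature_survival <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(set_id = x$set_id, direction = x$direction,
                   n_genes = length(x$gene_set)),
    x$logrank
  )
}
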