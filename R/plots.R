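#' Heatmap of per-stage adjusted correlations for significant pairs
#'
#' @param object A `synergy_scan` from [score_synergy()].
#' @param only_significant Show only significant pairs (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot synergy_scan
#' @export
autoplot.synergy_scan <- function(object, only_significant = TRUE, ...) {
  profiles <- object$profiles
  if (only_significant) {
    keep <- object$results[object$results$significant, c("lncrna", "mrna")]
    profiles <- dplyr::semi_join(profiles, keep, by = c("lncrna", "mrna"))
  }
  profiles <- dplyr::mutate(profiles,
                            pair = paste(.data$lncrna, .data$mrna, sep = "-"))
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = factor(.data$stage), y = .data$pair,
                               fill = .data$adjusted_r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = "stage", y = NULL, fill = "adjusted r",
                  title = "Stage-specific adjusted correlations") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for a signature-survival stratification
#'
#' @param object A `signature_survival` from [signature_survival()].
#' @param ... Unused.
#' @return A ggplot with one step curve per score group.
#' @method autoplot signature_survival
#' @export
autoplot.signature_survival <- function(object, ...) {
  d <- tidy(object)
  sf <- survival::survfit(survival::Surv(d$time, d$event) ~ d$group)
  strata <- rep(sub("^d\\$group=", "", names(sf$strata)), sf$strata)
  km <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1, group = unique(strata)),
    tibble::tibble(time = sf$time, surv = sf$surv, group = strata)
  )
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  colour = "PLAGE score",
                  title = paste0(object$set_id, " (", object$direction,
                                 "): log-rank p = ",
                                 signif(object$logrank$p, 3))) +
    ggplot2::theme_minimal()
}

#' Bar chart of co-expression pattern counts
#'
#' @param calls Output of [classify_patterns()].
#' @return A ggplot.
#' @export
plot_pattern_distribution <- function(calls) {
  calls <- tibble::as_tibble(calls)
  calls$pattern <- factor(calls$pattern,
                          levels = c("early_specific", "advanced_specific",
                                     "stage_common", "stage_converted"))
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$pattern)) +
    ggplot2::geom_bar(fill = "#4292C6") +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = NULL, y = "pairs",
                  title = "Cross-stage co-expression patterns") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Spot map of a pair's presence pattern
#'
#' Colours each spot by which of the two entities are present, the visual
#' companion of [call_pairs()].
#'
#' @param counts Spots x genes count matrix.
#' @param coords Tibble with `spot`, `x`, `y`.
#' @param entity1,entity2 Gene ids.
#' @param threshold Presence cutoff (default 0).
#' @return A ggplot.
#' @export
plot_spot_pair <- function(counts, coords, entity1, entity2, threshold = 0) {
  p1 <- binarize_spots(counts, entity1, threshold)
  p2 <- binarize_spots(counts, entity2, threshold)
  coords <- tibble::as_tibble(coords)
  coords$state <- dplyr::case_when(
    p1[coords$spot] & p2[coords$spot] ~ "both",
    p1[coords$spot] ~ entity1,
    p2[coords$spot] ~ entity2,
    TRUE ~ "neither"
  )
  ggplot2::ggplot(coords, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste(entity1, "vs", entity2), fill = NULL) +
    ggplot2::theme_minimal()
}
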