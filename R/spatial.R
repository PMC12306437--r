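#' Presence of a gene across spatial spots
#'
#' A gene is present in a spot when its count strictly exceeds `threshold`
#' (default 0: any positive count, the natural rule for sparse spot-level
#' data). Raising the threshold can only shrink the presence set.
#'
#' @param counts Spots x genes non-negative count matrix (spot ids as
#'   rownames).
#' @param entity Gene id (a column of `counts`).
#' @param threshold Presence cutoff (count must be `> threshold`).
#' @return Named logical vector over spots.
#' @export
binarize_spots <- function(counts, entity, threshold = 0) {
  stopifnot(is.matrix(counts))
  if (!entity %in% colnames(counts)) {
    stop("entity '", entity, "' not found in the count matrix", call. = FALSE)
  }
  counts[, entity] > threshold
}

#' Two-sided Fisher's exact p-value for a 2x2 spot table
#'
#' Exact test on the contingency table (`a` both present, `b` first only,
#' `c` second only, `d` neither) by summation over all tables with the
#' observed margins whose point hypergeometric probability does not exceed
#' the observed one (the standard two-sided convention, via
#' [stats::fisher.test()]); `alternative = "greater"`/`"less"` give the
#' one-sided hypergeometric tails. Both margins must be non-degenerate:
#' each entity present in at least one spot and absent in at least one.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return The p-value.
#' @examples
#' fisher_cooccurrence_p(5, 0, 0, 5)  # 2/252
#' @export
fisher_cooccurrence_p <- function(a, b, c, d,
                                  alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d >= 1)
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    stop("undefined test: a margin of the 2x2 table is zero ",
         "(an entity is present everywhere or nowhere)", call. = FALSE)
  }
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2),
                     alternative = alternative)$p.value
}

resolve_presence <- function(entity, counts, cell_scores, threshold,
                             score_quantile) {
  if (!is.null(counts) && entity %in% colnames(counts)) {
    return(binarize_spots(counts, entity, threshold))
  }
  if (!is.null(cell_scores) && entity %in% colnames(cell_scores)) {
    sc <- cell_scores[, entity]
    # enrichment scores have no absolute zero: present above the
    # per-sample quantile (default median)
    return(sc > stats::quantile(sc, score_quantile, names = FALSE))
  }
  stop("entity '", entity, "' found neither among genes nor cell types",
       call. = FALSE)
}

#' Call co-occurrence or mutual exclusivity for entity pairs across spots
#'
#' Builds the 2x2 presence table for each pair of entities (genes, or cell
#' types via their spot scores), computes the Fisher exact p-value and the
#' ratio `(a + d) / (b + c)` (`Inf` when `b + c = 0`), and calls
#' `cooccurrence` when `p < alpha` and ratio > 1, `exclusivity` when
#' `p < alpha` and ratio < 1, and `none` otherwise (including ratio = 1).
#' The call is symmetric in the two entities.
#'
#' @param pairs Data frame with columns `entity1`, `entity2`.
#' @param counts Spots x genes count matrix (optional if all entities are
#'   cell types).
#' @param cell_scores Optional spots x cell-types score matrix; a cell type
#'   is present in a spot when its score exceeds the `score_quantile`
#'   quantile of that cell type's scores.
#' @param alpha Significance threshold (default 0.05).
#' @param threshold Gene presence count cutoff (default 0).
#' @param alternative Sidedness of the Fisher test (default two-sided).
#' @param score_quantile Presence quantile for cell-type scores
#'   (default 0.5, the per-sample median).
#' @return Tibble with `entity1`, `entity2`, `a`, `b`, `c`, `d`, `n`,
#'   `fisher_p`, `ratio`, `call`.
#' @export
call_pairs <- function(pairs, counts = NULL, cell_scores = NULL,
                       alpha = 0.05, threshold = 0,
                       alternative = "two.sided", score_quantile = 0.5) {
  pairs <- tibble::as_tibble(pairs)[, c("entity1", "entity2")]
  purrr::pmap(pairs, function(entity1, entity2) {
    p1 <- resolve_presence(entity1, counts, cell_scores, threshold,
                           score_quantile)
    p2 <- resolve_presence(entity2, counts, cell_scores, threshold,
                           score_quantile)
    a <- sum(p1 & p2); b <- sum(p1 & !p2)
    c <- sum(!p1 & p2); d <- sum(!p1 & !p2)
    fp <- fisher_cooccurrence_p(a, b, c, d, alternative)
    ratio <- if (b + c == 0) Inf else (a + d) / (b + c)
    call <- if (fp < alpha && ratio > 1) "cooccurrence"
            else if (fp < alpha && ratio < 1) "exclusivity"
            else "none"
    tibble::tibble(entity1 = entity1, entity2 = entity2,
                   a = a, b = b, c = c, d = d, n = a + b + c + d,
                   fisher_p = fp, ratio = ratio, call = call)
  }) |>
    dplyr::bind_rows()
}

#' Marker-based cell-type scores for spatial spots
#'
#' A light-weight spot-level cell-type score: counts are library-size
#' normalised per spot (counts per 10k), log1p-transformed, averaged over
#' each cell type's marker genes, and z-scored across spots. A cell type
#' whose score is constant across spots (e.g. markers absent everywhere) is
#' degenerate: its score is set to 0 and it is reported in the
#' `degenerate` attribute with a warning.
#'
#' @param counts Spots x genes count matrix.
#' @param marker_sets Data frame with columns `cell_type`, `gene`.
#' @return Spots x cell-types score matrix (attribute `degenerate` lists
#'   constant cell types).
#' @export
score_spot_celltypes <- function(counts, marker_sets) {
  stopifnot(is.matrix(counts))
  marker_sets <- tibble::as_tibble(marker_sets)[, c("cell_type", "gene")]
  lib <- pmax(rowSums(counts), 1)
  logn <- log1p(sweep(counts, 1, lib, "/") * 1e4)
  types <- unique(marker_sets$cell_type)
  out <- matrix(0, nrow(counts), length(types),
                dimnames = list(rownames(counts), types))
  degenerate <- character()
  for (ct in types) {
    mk <- intersect(marker_sets$gene[marker_sets$cell_type == ct],
                    colnames(counts))
    score <- if (length(mk)) rowMeans(logn[, mk, drop = FALSE]) else
      rep(0, nrow(counts))
    if (stats::sd(score) == 0) {
      degenerate <- c(degenerate, ct)
    } else {
      out[, ct] <- as.numeric(scale(score))
    }
  }
  if (length(degenerate)) {
    warning("degenerate (constant) cell-type score(s): ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  }
  attr(out, "degenerate") <- degenerate
  out
}
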