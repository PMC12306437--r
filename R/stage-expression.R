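#' Stage-labelled expression container
#'
#' Bundles a genes x samples log-expression matrix with per-sample tumour
#' stage labels and a per-gene class annotation (lncRNA or mRNA, plus an
#' immune-checkpoint flag). All downstream correlation and filtering steps
#' operate on this object; expression values are assumed already normalised
#' and log-scaled upstream and are never transformed here.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Log-scale expression.
#' @param sample_stage Data frame with columns `sample` and `stage`
#'   (integer-coded ordinal stage, e.g. 1..4), one row per matrix column.
#' @param gene_class Data frame with columns `gene`, `class` (`"lncRNA"` or
#'   `"mRNA"`) and logical `is_icp`, covering every matrix row.
#' @return An object of class `stage_expr`.
#' @examples
#' m <- matrix(rnorm(12), 2, 6, dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
#' ss <- data.frame(sample = paste0("s", 1:6), stage = rep(1:2, each = 3))
#' gc <- data.frame(gene = c("g1", "g2"), class = c("lncRNA", "mRNA"),
#'                  is_icp = c(FALSE, TRUE))
#' stage_expression(m, ss, gc)
#' @export
stage_expression <- function(values, sample_stage, gene_class) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids", call. = FALSE)
  sample_stage <- tibble::as_tibble(sample_stage)
  gene_class <- tibble::as_tibble(gene_class)
  stopifnot(all(c("sample", "stage") %in% names(sample_stage)),
            all(c("gene", "class") %in% names(gene_class)))
  if (!"is_icp" %in% names(gene_class)) gene_class$is_icp <- FALSE
  if (anyDuplicated(sample_stage$sample)) stop("duplicate samples in `sample_stage`", call. = FALSE)
  missing_s <- setdiff(colnames(values), sample_stage$sample)
  if (length(missing_s)) {
    stop("samples without a stage label: ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  }
  missing_g <- setdiff(rownames(values), gene_class$gene)
  if (length(missing_g)) {
    stop("genes without a class: ", paste(utils::head(missing_g, 5), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(values))) stop("expression values must be finite", call. = FALSE)
  sample_stage <- sample_stage[match(colnames(values), sample_stage$sample), ]
  gene_class <- gene_class[gene_class$gene %in% rownames(values), ]
  structure(
    list(values = values,
         sample_stage = sample_stage[, c("sample", "stage")],
         gene_class = gene_class[, c("gene", "class", "is_icp")]),
    class = "stage_expr"
  )
}

#' @export
print.stage_expr <- function(x, ...) {
  st <- table(x$sample_stage$stage)
  cl <- table(x$gene_class$class)
  cat("<stage_expr> ", nrow(x$values), " genes x ", ncol(x$values), " samples\n",
      sep = "")
  cat("  stages: ", paste0(names(st), " (n=", st, ")", collapse = ", "), "\n", sep = "")
  cat("  genes:  ", paste0(names(cl), " (", cl, ")", collapse = ", "),
      "; ICP-flagged: ", sum(x$gene_class$is_icp), "\n", sep = "")
  invisible(x)
}

#' @export
dim.stage_expr <- function(x) dim(x$values)

#' Per-sample stage labels as an integer vector aligned to matrix columns
#' @param expr A `stage_expr` object.
#' @return Integer vector, one stage per sample column.
#' @keywords internal
#' @noRd
stage_vector <- function(expr) {
  as.integer(expr$sample_stage$stage)
}

#' Drop stages with too few samples
#'
#' Retains only samples belonging to stages represented by strictly more
#' than `min_cases` samples (the catalogue-building rule is >10 cases per
#' stage). The stage-specificity score needs at least two surviving stages
#' (its denominator is N - 1), so fewer than two is an error.
#'
#' @param expr A [stage_expression()] object.
#' @param min_cases Keep a stage only if it has strictly more than this many
#'   samples (default 10).
#' @return A `stage_expr` with the offending samples removed. Idempotent.
#' @examples
#' m <- matrix(rnorm(3 * 36), 3, 36,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:36)))
#' ss <- data.frame(sample = paste0("s", 1:36),
#'                  stage = rep(1:3, times = c(12, 15, 9)))
#' gc <- data.frame(gene = paste0("g", 1:3), class = "mRNA", is_icp = FALSE)
#' fe <- filter_stages(stage_expression(m, ss, gc), min_cases = 10)
#' table(fe$sample_stage$stage)  # stage 3 dropped, 27 samples kept
#' @export
filter_stages <- function(expr, min_cases = 10) {
  stopifnot(inherits(expr, "stage_expr"), min_cases >= 1)
  counts <- table(expr$sample_stage$stage)
  keep_stages <- names(counts)[counts > min_cases]
  if (length(keep_stages) < 2) {
    stop("insufficient stages: only ", length(keep_stages),
         " stage(s) have > ", min_cases,
         " samples; at least 2 are required", call. = FALSE)
  }
  keep <- expr$sample_stage$stage %in% as.integer(keep_stages)
  stage_expression(expr$values[, keep, drop = FALSE],
                   expr$sample_stage[keep, ],
                   expr$gene_class)
}
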