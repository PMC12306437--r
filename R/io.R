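# TSV readers and writers for the pipeline's on-disk interfaces.
# Every writer can prepend '#'-comment header lines (run provenance);
# every reader skips them.

write_tsv_commented <- function(df, path, header = character()) {
  if (length(header)) readr::write_lines(paste0("# ", header), path)
  readr::write_tsv(df, path, append = length(header) > 0, col_names = TRUE)
  invisible(path)
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

#' Write / read a stage-labelled expression bundle as TSV
#'
#' Three files: expression (`gene` column then one column per sample),
#' clinical (`sample`, `stage`) and gene catalogue (`gene`, `class`,
#' `is_icp`).
#'
#' @param expr A [stage_expression()].
#' @param expr_path,clinical_path,catalog_path Output file paths.
#' @param header Optional comment lines (without the leading `#`).
#' @return `expr_path`, invisibly.
#' @export
write_expression_tsv <- function(expr, expr_path, clinical_path,
                                 catalog_path, header = character()) {
  stopifnot(inherits(expr, "stage_expr"))
  df <- dplyr::bind_cols(tibble::tibble(gene = rownames(expr$values)),
                         tibble::as_tibble(expr$values))
  write_tsv_commented(df, expr_path, header)
  write_tsv_commented(expr$sample_stage, clinical_path, header)
  write_tsv_commented(expr$gene_class, catalog_path, header)
  invisible(expr_path)
}

#' @rdname write_expression_tsv
#' @return For the reader: the reconstructed `stage_expr`.
#' @export
read_expression_tsv <- function(expr_path, clinical_path, catalog_path) {
  df <- read_tsv_quiet(expr_path)
  values <- as.matrix(df[, -1])
  rownames(values) <- df$gene
  stage_expression(values,
                   read_tsv_quiet(clinical_path),
                   read_tsv_quiet(catalog_path))
}

#' Write all inputs of a simulated study to a directory
#'
#' Emits the full set of pipeline input files: expression/clinical/gene
#' catalogue, PPI edges, interaction catalogue, ICP list, cell scores,
#' spatial counts (long `spot`, `x`, `y`, `gene`, `count` format for
#' nonzero entries), marker sets, survival table and the ground-truth
#' tables.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_tsv <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_expression_tsv(study$expr, p("expression.tsv"), p("clinical.tsv"),
                       p("gene_catalog.tsv"))
  write_tsv_commented(study$ppi, p("ppi.tsv"))
  write_tsv_commented(study$catalog, p("interactions.tsv"))
  readr::write_lines(study$icps, p("icp_genes.txt"))
  cs <- dplyr::bind_cols(
    tibble::tibble(cell_type = rownames(study$cell_scores)),
    tibble::as_tibble(study$cell_scores)
  )
  write_tsv_commented(cs, p("cell_scores.tsv"))
  sp <- study$spatial
  long <- tibble::as_tibble(as.data.frame(as.table(sp$counts),
                                          stringsAsFactors = FALSE))
  names(long) <- c("spot", "gene", "count")
  long <- dplyr::filter(long, .data$count > 0)
  long <- dplyr::left_join(long, sp$coords, by = "spot")
  write_tsv_commented(long[, c("spot", "x", "y", "gene", "count")],
                      p("spatial_counts.tsv"))
  write_tsv_commented(sp$coords, p("spatial_coords.tsv"))
  write_tsv_commented(sp$markers, p("spatial_markers.tsv"))
  write_tsv_commented(sp$truth, p("spatial_truth.tsv"))
  write_tsv_commented(study$survival, p("survival.tsv"))
  write_tsv_commented(study$truth, p("pair_truth.tsv"))
  invisible(dir)
}

#' Read a long-format spatial counts TSV back into a matrix
#'
#' @param counts_path Long TSV with `spot`, `x`, `y`, `gene`, `count`.
#' @param coords_path Optional coordinates TSV (`spot`, `x`, `y`); defaults
#'   to the coordinates embedded in the counts file.
#' @return List with `counts` (spots x genes matrix) and `coords` tibble.
#' @export
read_spatial_tsv <- function(counts_path, coords_path = NULL) {
  long <- read_tsv_quiet(counts_path)
  coords <- if (is.null(coords_path)) {
    dplyr::distinct(long[, c("spot", "x", "y")])
  } else {
    read_tsv_quiet(coords_path)
  }
  spots <- coords$spot
  genes <- sort(unique(long$gene))
  counts <- matrix(0L, length(spots), length(genes),
                   dimnames = list(spots, genes))
  counts[cbind(match(long$spot, spots), match(long$gene, genes))] <-
    as.integer(long$count)
  list(counts = counts, coords = coords)
}

#' Read a one-id-per-line gene list
#' @param path Text file, one gene id per line (blank lines and `#`
#'   comments ignored).
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}
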