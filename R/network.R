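#' ICP genes and their first PPI neighbours
#'
#' Returns the union of the immune-checkpoint genes and every gene sharing a
#' PPI edge with at least one of them. "Interacting proteins" is read as
#' first neighbours (PPI distance <= 1); genes at distance 2 are excluded.
#'
#' @param ppi Data frame of undirected edges with columns `gene_a`, `gene_b`.
#' @param icps Character vector of immune-checkpoint gene ids.
#' @return Character vector of gene ids (the ICPs plus their neighbours).
#' @examples
#' ppi <- data.frame(gene_a = c("ICP1", "g1"), gene_b = c("g1", "g2"))
#' icp_neighborhood(ppi, "ICP1")  # "ICP1" "g1"; g2 is distance 2
#' @export
icp_neighborhood <- function(ppi, icps) {
  if (length(icps) == 0) stop("empty ICP set", call. = FALSE)
  ppi <- tibble::as_tibble(ppi)
  stopifnot(all(c("gene_a", "gene_b") %in% names(ppi)))
  nb <- c(ppi$gene_b[ppi$gene_a %in% icps], ppi$gene_a[ppi$gene_b %in% icps])
  sort(unique(c(icps, nb)))
}

#' The ICPs a gene equals or neighbours, per gene
#' @return Named list gene -> character vector of anchor ICPs.
#' @noRd
anchor_icp_map <- function(ppi, icps) {
  ppi <- tibble::as_tibble(ppi)
  edges <- dplyr::bind_rows(
    tibble::tibble(gene = ppi$gene_a, icp = ppi$gene_b),
    tibble::tibble(gene = ppi$gene_b, icp = ppi$gene_a)
  )
  edges <- dplyr::filter(edges, .data$icp %in% icps)
  edges <- dplyr::bind_rows(edges, tibble::tibble(gene = icps, icp = icps))
  edges <- dplyr::distinct(edges)
  split(edges$icp, edges$gene)
}

#' Kruskal-Wallis p-value for stage-differential expression
#'
#' Tie-corrected Kruskal-Wallis rank-sum test of a gene's expression across
#' stage groups (chi-square reference with `n_stages - 1` df), via
#' [stats::kruskal.test()]. When every observation is identical the
#' tie-corrected statistic is undefined; p = 1 is returned by convention
#' (such a gene cannot be stage-differential).
#'
#' @param values Numeric vector of per-sample expression.
#' @param stages Per-sample stage labels (same length).
#' @return A single p-value.
#' @export
kruskal_wallis_p <- function(values, stages) {
  stopifnot(length(values) == length(stages))
  stages <- factor(stages)
  if (nlevels(stages) < 2) stop("need >= 2 stages", call. = FALSE)
  if (length(unique(values)) == 1) return(1)
  stats::kruskal.test(values, stages)$p.value
}

#' Build candidate lncRNA-mRNA pairs anchored to immune checkpoints
#'
#' Restricts the interaction catalogue to pairs whose mRNA is an ICP or a
#' first PPI neighbour of one, annotates each with its anchor ICPs and the
#' Kruskal-Wallis stage-differential p-values of both genes, and retains a
#' pair iff at least one member is stage-differential
#' (`min(kw_p_lnc, kw_p_mrna) < kw_alpha`). Genes missing from the
#' expression matrix are dropped with a warning. KW p-values are cached per
#' gene, so genes shared by many pairs are tested once.
#'
#' @param expr A stage-filtered [stage_expression()].
#' @param ppi PPI edge list (`gene_a`, `gene_b`).
#' @param catalog Interaction catalogue (`lncrna`, `mrna`).
#' @param icps Character vector of ICP gene ids.
#' @param kw_alpha Retention threshold on the smaller KW p-value
#'   (default 0.05, raw, uncorrected).
#' @return Tibble with `lncrna`, `mrna`, `anchor_icps` (semicolon-joined),
#'   `kw_p_lnc`, `kw_p_mrna`. A subset of `catalog`; possibly empty (with a
#'   warning), never an error.
#' @export
build_candidates <- function(expr, ppi, catalog, icps, kw_alpha = 0.05) {
  stopifnot(inherits(expr, "stage_expr"), kw_alpha > 0, kw_alpha < 1)
  catalog <- dplyr::distinct(tibble::as_tibble(catalog)[, c("lncrna", "mrna")])
  genes_present <- rownames(expr$values)
  missing <- setdiff(unique(c(catalog$lncrna, catalog$mrna)), genes_present)
  if (length(missing)) {
    warning(length(missing), " catalogue gene(s) absent from the expression",
            " matrix were dropped: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "", call. = FALSE)
    catalog <- dplyr::filter(catalog, .data$lncrna %in% genes_present,
                             .data$mrna %in% genes_present)
  }
  hood <- icp_neighborhood(ppi, icps)
  catalog <- dplyr::filter(catalog, .data$mrna %in% hood)
  if (nrow(catalog) == 0) {
    warning("no catalogue pair has an ICP-anchored mRNA", call. = FALSE)
    return(tibble::tibble(lncrna = character(), mrna = character(),
                          anchor_icps = character(), kw_p_lnc = double(),
                          kw_p_mrna = double()))
  }
  stages <- stage_vector(expr)
  kw_genes <- sort(unique(c(catalog$lncrna, catalog$mrna)))
  kw_cache <- vapply(kw_genes,
                     function(g) kruskal_wallis_p(expr$values[g, ], stages),
                     numeric(1))
  anchors <- anchor_icp_map(ppi, icps)
  out <- dplyr::mutate(
    catalog,
    anchor_icps = vapply(.data$mrna,
                         function(g) paste(sort(anchors[[g]]), collapse = ";"),
                         character(1), USE.NAMES = FALSE),
    kw_p_lnc = unname(kw_cache[.data$lncrna]),
    kw_p_mrna = unname(kw_cache[.data$mrna])
  )
  out <- dplyr::filter(out, pmin(.data$kw_p_lnc, .data$kw_p_mrna) < kw_alpha)
  out <- dplyr::arrange(out, .data$lncrna, .data$mrna)
  if (nrow(out) == 0) {
    warning("no candidate pair passed the Kruskal-Wallis filter", call. = FALSE)
  }
  out
}
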