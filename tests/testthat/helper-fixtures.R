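# in-code fixtures shared across test files

# stage_expr from a bare matrix and a stage vector
make_expr <- function(values, stages, class = NULL, icp = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  }
  if (is.null(class)) class <- rep("mRNA", nrow(values))
  if (is.null(icp)) icp <- rep(FALSE, nrow(values))
  stage_expression(
    values,
    data.frame(sample = colnames(values), stage = stages),
    data.frame(gene = rownames(values), class = class, is_icp = icp)
  )
}

# a small, fast simulation used where the full reference config is overkill
tiny_sim_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, samples_per_stage = c(30L, 30L, 30L),
         n_lncrna = 20, n_mrna = 30, n_icp = 3,
         n_planted_specific = 3, n_planted_uniform = 2, n_null_pairs = 5,
         n_decoy_pairs = 4, n_decoy_edges = 10,
         n_cell_types = 4, n_planted_cell_assoc = 2,
         spatial = list(grid_side = 12, n_cooccur = 2, n_exclusive = 2,
                        n_background_genes = 6)),
    list(...)
  )
  do.call(synergy_sim_config, args)
}

# independently coded evaluation of the stage-specificity score, kept
# deliberately literal (explicit loop over stages)
oracle_ssliss <- function(adjusted) {
  m <- 0
  for (a in adjusted) if (abs(a) > m) m <- abs(a)
  if (m == 0) return(0)
  total <- 0
  for (a in adjusted) total <- total + (1 - abs(a) / m)
  total / (length(adjusted) - 1) * (m / 0.75)
}
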