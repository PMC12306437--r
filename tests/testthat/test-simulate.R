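test_that("generators are deterministic under a fixed seed", {
  cfg <- tiny_sim_config(seed = 42)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_cell_scores(cfg, a$expr)$scores,
                   simulate_cell_scores(cfg, b$expr)$scores)
  expect_identical(simulate_spatial(cfg)$counts, simulate_spatial(cfg)$counts)
  sc <- stats::setNames(rnorm(10), sprintf("S%04d", 1:10))
  expect_identical(simulate_survival(cfg, sc), simulate_survival(cfg, sc))
  expect_false(identical(
    a$expr$values, simulate_expression(tiny_sim_config(seed = 43))$expr$values))
})

test_that("expression values are finite and marginals are per-stage normal", {
  ex <- simulate_expression(tiny_sim_config(seed = 3))
  expect_true(all(is.finite(ex$expr$values)))
  expect_identical(dim(ex$expr$values), c(50L, 90L))
})

test_that("planted specific pairs hit the target correlation in their active stage only", {
  cfg <- synergy_sim_config(seed = 9, samples_per_stage = c(200, 200, 200))
  ex <- simulate_expression(cfg)
  stages <- ex$expr$sample_stage$stage
  spec <- ex$truth[ex$truth$planted_class == "specific", ]
  expect_gte(nrow(spec), 20)
  for (i in seq_len(nrow(spec))) {
    for (st in 1:3) {
      r <- cor(ex$expr$values[spec$lncrna[i], stages == st],
               ex$expr$values[spec$mrna[i], stages == st])
      if (st == spec$active_stage[i]) {
        expect_gt(r, 0.7); expect_lt(r, 0.9)
      } else {
        expect_lt(abs(r), 0.2)
      }
    }
  }
})

test_that("with nothing planted, per-stage correlations behave as a null", {
  cfg <- synergy_sim_config(seed = 21, samples_per_stage = c(200, 200, 200),
                            n_planted_specific = 0, n_planted_uniform = 0,
                            n_null_pairs = 200, n_lncrna = 200, n_mrna = 220,
                            n_decoy_pairs = 0, n_decoy_edges = 0)
  ex <- simulate_expression(cfg)
  stages <- ex$expr$sample_stage$stage
  rs <- unlist(lapply(seq_len(nrow(ex$truth)), function(i) {
    sapply(1:3, function(st) {
      cor(ex$expr$values[ex$truth$lncrna[i], stages == st],
          ex$expr$values[ex$truth$mrna[i], stages == st])
    })
  }))
  expect_true(all(abs(rs) < 0.5))
  # share with two-sided Pearson p < 0.05 stays in a 3-sigma binomial band
  n <- 200
  tt <- abs(rs) * sqrt((n - 2) / (1 - rs^2))
  hits <- mean(2 * pt(-tt, n - 2) < 0.05)
  expect_lt(abs(hits - 0.05), 3 * sqrt(0.05 * 0.95 / length(rs)))
})

test_that("network anchors every catalogued pair's mRNA to an ICP", {
  cfg <- tiny_sim_config(seed = 5)
  net <- simulate_network(cfg)
  hood <- icp_neighborhood(net$ppi, net$icps)
  truth <- simulate_expression(cfg)$truth
  expect_true(all(truth$mrna %in% hood))
  expect_identical(nrow(net$catalog), nrow(dplyr::distinct(net$catalog)))
  # decoy pairs stay unanchored by construction
  decoys <- dplyr::anti_join(net$catalog, truth, by = c("lncrna", "mrna"))
  expect_identical(nrow(decoys), 4L)
  expect_false(any(decoys$mrna %in% hood))
})

test_that("catalogue size without decoys is the planted pair count", {
  cfg <- tiny_sim_config(seed = 5)
  net <- simulate_network(cfg, decoys = FALSE)
  expect_identical(nrow(net$catalog), 3L + 2L + 5L)
})

test_that("cell scores carry the planted monotone associations", {
  cfg <- tiny_sim_config(seed = 8, samples_per_stage = c(70, 70, 70))
  ex <- simulate_expression(cfg)
  cells <- simulate_cell_scores(cfg, ex$expr)
  for (i in seq_len(nrow(cells$truth))) {
    rho <- cor(ex$expr$values[cells$truth$gene[i], ],
               cells$scores[cells$truth$cell_type[i], ],
               method = "spearman")
    expect_gt(rho * cells$truth$direction[i], 0.5)
  }
  # unplanted combinations are null: |rho| < 0.2 in >= 95% of cases
  unplanted <- setdiff(rownames(cells$scores), cells$truth$cell_type)
  rhos <- sapply(unplanted, function(ct) {
    sapply(ex$truth$lncrna, function(g) {
      cor(ex$expr$values[g, ], cells$scores[ct, ], method = "spearman")
    })
  })
  expect_gte(mean(abs(rhos) < 0.2), 0.95)
})

test_that("spatial generator plants the right contingency structure", {
  cfg <- tiny_sim_config(seed = 13)
  sp <- simulate_spatial(cfg)
  expect_identical(nrow(sp$counts), 12L * 12L)
  for (i in seq_len(nrow(sp$truth))) {
    p1 <- sp$counts[, sp$truth$gene1[i]] > 0
    p2 <- sp$counts[, sp$truth$gene2[i]] > 0
    a <- sum(p1 & p2); d <- sum(!p1 & !p2)
    bc <- sum(xor(p1, p2))
    ratio <- (a + d) / bc
    if (sp$truth$relation[i] == "cooccurrence") expect_gt(ratio, 1)
    else expect_lt(ratio, 1)
  }
})

test_that("survival times carry the planted hazard effect", {
  cfg <- tiny_sim_config(seed = 2)
  score <- stats::setNames(rnorm(300), sprintf("P%03d", 1:300))
  surv <- simulate_survival(cfg, score)
  expect_identical(nrow(surv), 300L)
  expect_true(all(surv$time >= 0) && all(surv$event %in% 0:1))
  # strong positive effect: high-score half dies faster
  grp <- median_split(score)
  lr <- logrank_test(surv, grp)
  expect_lt(lr$p, 0.01)
  med <- tapply(surv$time[surv$event == 1], grp[surv$event == 1], median)
  expect_lt(med[["high"]], med[["low"]])
})

test_that("a fully censored cohort yields a zero log-rank statistic", {
  surv <- tibble::tibble(sample = sprintf("P%02d", 1:10),
                         time = rep(100, 10), event = rep(0L, 10))
  grp <- factor(rep(c("low", "high"), 5), levels = c("low", "high"))
  expect_warning(lr <- logrank_test(surv, grp), "no events")
  expect_identical(lr$chi2, 0)
  expect_identical(lr$p, 1)
})
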