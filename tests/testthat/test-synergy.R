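test_that("stage correlations match the textbook formula and the adjustment rule", {
  # two stages with printed vectors; stage 1 exactly linear
  x1 <- 1:10
  y1 <- 2 * x1 + 1
  x2 <- c(1.2, -0.4, 0.8, 2.1, -1.3, 0.5, 1.7, -0.9, 0.3, 0.6)
  y2 <- c(0.4, 1.1, -0.7, 0.2, 0.9, -1.5, 0.8, 0.1, -0.3, 1.3)
  vals <- rbind(lnc = c(x1, x2), mrna = c(y1, y2))
  e <- make_expr(vals, rep(1:2, each = 10), class = c("lncRNA", "mRNA"))
  prof <- stage_correlations(e, data.frame(lncrna = "lnc", mrna = "mrna"))
  expect_equal(prof$r[prof$stage == 1], 1, tolerance = 1e-12)
  expect_equal(prof$adjusted_r[prof$stage == 1], 1, tolerance = 1e-12)

  # brute-force covariance / sigma oracle for stage 2
  r_oracle <- sum((x2 - mean(x2)) * (y2 - mean(y2))) /
    sqrt(sum((x2 - mean(x2))^2) * sum((y2 - mean(y2))^2))
  expect_equal(prof$r[prof$stage == 2], r_oracle, tolerance = 1e-12)
  # p-values agree with cor.test
  ct <- cor.test(x2, y2)
  expect_equal(prof$p[prof$stage == 2], ct$p.value, tolerance = 1e-12)
  # non-significant correlation is zeroed
  expect_true(ct$p.value >= 0.05)
  expect_identical(prof$adjusted_r[prof$stage == 2], 0)
})

test_that("zero-variance genes give r = 0, p = 1 with a warning", {
  vals <- rbind(lnc = c(rep(5, 10), rnorm(10)), mrna = rnorm(20))
  e <- make_expr(vals, rep(1:2, each = 10), class = c("lncRNA", "mRNA"))
  expect_warning(
    prof <- stage_correlations(e, data.frame(lncrna = "lnc", mrna = "mrna")),
    "zero-variance")
  expect_identical(prof$r[prof$stage == 1], 0)
  expect_identical(prof$p[prof$stage == 1], 1)
})

test_that("ssliss reproduces its closed forms", {
  expect_identical(ssliss(c(0.6, 0.6, 0.6)), 0)
  expect_equal(ssliss(c(0.75, 0, 0, 0)), 1, tolerance = 1e-12)
  expect_equal(ssliss(c(0.75, 0.3, 0)), 0.8, tolerance = 1e-12)
  expect_identical(ssliss(c(0, 0, 0)), 0)
  expect_error(ssliss(0.5), "at least 2 stages")
})

test_that("ssliss matches an independent evaluation and stays in range", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    adj <- runif(n, -1, 1) * rbinom(n, 1, 0.6)
    s <- ssliss(adj)
    expect_equal(s, oracle_ssliss(adj), tolerance = 1e-12)
    expect_gte(s, 0)
    expect_lte(s, 4 / 3 + 1e-12)
  }
  # single significant stage: exact closed form max/0.75
  for (i in 1:50) {
    n <- sample(2:6, 1)
    adj <- numeric(n)
    adj[sample(n, 1)] <- runif(1, -1, 1)
    expect_equal(ssliss(adj), max(abs(adj)) / 0.75, tolerance = 1e-12)
  }
})

test_that("specific stage is the argmax with earliest-stage tie-break", {
  expect_identical(assign_specific_stage(c(0.2, -0.9, 0.4)), 2L)
  expect_identical(assign_specific_stage(c(0.8, 0.8)), 1L)
  expect_true(is.na(assign_specific_stage(c(0, 0, 0))))
  expect_identical(assign_specific_stage(c(0, -0.5), stages = c(2L, 4L)), 4L)
})

test_that("permutation p-values honour the add-one convention", {
  set.seed(11)
  stages <- rep(1:3, each = 10)
  x <- rnorm(30)
  y <- rnorm(30)
  y[stages == 1] <- x[stages == 1]  # perfect correlation in stage 1 only
  vals <- rbind(lnc = x, mrna = y)
  e <- make_expr(vals, stages, class = c("lncRNA", "mRNA"))
  out <- permutation_pvalue(e, "lnc", "mrna", B = 1000, seed = 3)
  expect_equal(out$observed, ssliss(c(1, 0, 0)), tolerance = 1e-9)
  expect_identical(out$perm_p, 1 / 1001)

  # observed score of zero can never beat the null: p = 1 exactly
  x0 <- rep(1:10, 3)
  y0 <- rep(c(2:10, 1), 3)   # r ~ 0.45, p ~ 0.19 in every stage
  e0 <- make_expr(rbind(lnc = x0, mrna = y0), stages,
                  class = c("lncRNA", "mRNA"))
  out0 <- permutation_pvalue(e0, "lnc", "mrna", B = 100, seed = 3)
  expect_identical(out0$observed, 0)
  expect_identical(out0$perm_p, 1)
})

test_that("outputs are invariant to positive per-gene rescaling within stages", {
  cfg <- tiny_sim_config(seed = 23)
  st <- simulate_expression(cfg)
  pair <- st$truth[1, c("lncrna", "mrna")]
  prof1 <- stage_correlations(st$expr, pair)
  scaled <- st$expr
  scaled$values[pair$lncrna, ] <- 3.7 * scaled$values[pair$lncrna, ]
  scaled$values[pair$mrna, ] <- 0.2 * scaled$values[pair$mrna, ]
  prof2 <- stage_correlations(scaled, pair)
  expect_equal(prof1$r, prof2$r, tolerance = 1e-12)
  expect_equal(prof1$p, prof2$p, tolerance = 1e-12)
})

test_that("score_synergy is deterministic and candidate-order independent", {
  cfg <- tiny_sim_config(seed = 29)
  st <- simulate_expression(cfg)
  cand <- st$truth[, c("lncrna", "mrna")]
  a <- score_synergy(st$expr, cand, B = 50, seed = 5)
  b <- score_synergy(st$expr, cand, B = 50, seed = 5)
  expect_identical(a$results, b$results)
  flipped <- score_synergy(st$expr, cand[rev(seq_len(nrow(cand))), ],
                           B = 50, seed = 5)
  reordered <- flipped$results[match(paste(a$results$lncrna, a$results$mrna),
                                     paste(flipped$results$lncrna,
                                           flipped$results$mrna)), ]
  expect_equal(a$results$perm_p, reordered$perm_p, tolerance = 1e-15)
  expect_equal(a$results$ssliss, reordered$ssliss, tolerance = 1e-15)
})

test_that("an empty candidate list yields an empty scan, not an error", {
  cfg <- tiny_sim_config(seed = 2)
  st <- simulate_expression(cfg)
  scan <- score_synergy(st$expr, data.frame(lncrna = character(),
                                            mrna = character()), B = 10)
  expect_identical(nrow(scan$results), 0L)
  expect_identical(glance(scan)$n_significant, 0L)
})

test_that("significance combines the permutation p with a nonzero profile", {
  cfg <- tiny_sim_config(seed = 37, samples_per_stage = c(60, 60, 60))
  st <- simulate_expression(cfg)
  scan <- score_synergy(st$expr, st$truth[, c("lncrna", "mrna")],
                        B = 200, seed = 37)
  res <- dplyr::left_join(tidy(scan), st$truth, by = c("lncrna", "mrna"))
  spec <- res[res$planted_class == "specific", ]
  expect_true(all(spec$significant))
  expect_true(all(spec$specific_stage == spec$active_stage))
  expect_true(all(res$significant == (res$perm_p < 0.05 &
                                        res$max_abs_adjusted > 0)))
})
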