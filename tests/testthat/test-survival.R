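test_that("differential sets split by direction and drop flat genes", {
  vals <- rbind(up = c(rep(1, 30), rep(10, 10)),
                down = c(rep(10, 30), rep(1, 10)),
                flat = rep(3, 40))
  e <- make_expr(vals, rep(c(1, 4), c(30, 10)))
  sets <- stage_differential_sets(e, c("up", "down", "flat"), target_stage = 4)
  expect_identical(sets$up, "up")
  expect_identical(sets$down, "down")
  expect_error(stage_differential_sets(e, "ghost"), "empty gene universe")
})

test_that("planted 1-SD shifts are recovered with high recall", {
  set.seed(12)
  n1 <- 150; n4 <- 50
  shifted <- matrix(rnorm(30 * (n1 + n4)), 30)
  shifted[, (n1 + 1):(n1 + n4)] <- shifted[, (n1 + 1):(n1 + n4)] + 1
  nulls <- matrix(rnorm(10 * (n1 + n4)), 10)
  vals <- rbind(shifted, nulls)
  rownames(vals) <- c(sprintf("up%02d", 1:30), sprintf("null%02d", 1:10))
  e <- make_expr(vals, rep(c(1, 4), c(n1, n4)))
  sets <- stage_differential_sets(e, rownames(vals), target_stage = 4)
  expect_gte(length(intersect(sets$up, sprintf("up%02d", 1:30))) / 30, 0.9)
  expect_lte(length(setdiff(c(sets$up, sets$down), sprintf("up%02d", 1:30))),
             2)
})

test_that("PLAGE of a singleton set is the unit-normalised z-score", {
  set.seed(3)
  vals <- matrix(rnorm(3 * 20), 3, dimnames = list(c("g1", "g2", "g3"), NULL))
  sc <- plage_scores(vals, "g1")
  z <- as.numeric(scale(vals["g1", ]))
  expect_equal(unname(sc), z / sqrt(sum(z^2)), tolerance = 1e-10)
  expect_equal(sum(sc^2), 1, tolerance = 1e-12)
  # duplicating the gene keeps the same direction
  vals2 <- rbind(vals, g1b = vals["g1", ])
  sc2 <- plage_scores(vals2, c("g1", "g1b"))
  expect_equal(unname(sc2), z / sqrt(sum(z^2)), tolerance = 1e-10)
})

test_that("PLAGE matches a dense SVD oracle up to the documented orientation", {
  set.seed(8)
  for (i in 1:5) {
    vals <- matrix(rnorm(5 * 30), 5,
                   dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:30)))
    sc <- plage_scores(vals, rownames(vals))
    z <- t(scale(t(vals)))
    v1 <- svd(z)$v[, 1]
    if (cor(v1, colMeans(z)) < 0) v1 <- -v1
    expect_equal(unname(sc), v1, tolerance = 1e-10)
  }
})

test_that("PLAGE is invariant to per-gene affine rescaling", {
  set.seed(9)
  vals <- matrix(rnorm(4 * 25), 4, dimnames = list(sprintf("g%d", 1:4), NULL))
  rescaled <- vals * c(2, 5, 0.1, 7) + c(-3, 0, 11, 2)
  expect_equal(unname(plage_scores(vals, rownames(vals))),
               unname(plage_scores(rescaled, rownames(vals))),
               tolerance = 1e-10)
})

test_that("zero-variance set members are dropped with a warning", {
  vals <- rbind(g1 = rnorm(10), g2 = rep(1, 10))
  colnames(vals) <- sprintf("s%d", 1:10)
  expect_warning(sc <- plage_scores(vals, c("g1", "g2")), "zero-variance")
  expect_length(sc, 10)
  expect_error(suppressWarnings(plage_scores(vals, "g2")), "zero variance")
})

test_that("median split sends ties and the odd median sample to low", {
  s <- c(a = 1, b = 2, c = 3, d = 4)
  g <- median_split(s)
  expect_identical(as.character(g[c("a", "b")]), c("low", "low"))
  expect_identical(as.character(g[c("c", "d")]), c("high", "high"))

  s5 <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  g5 <- median_split(s5)
  expect_identical(as.character(g5[["c"]]), "low")
  expect_identical(unname(table(g5)["low"]), 3L)

  g_all <- median_split(c(a = 2, b = 2, c = 2))
  expect_true(all(g_all == "low"))
  surv <- tibble::tibble(sample = c("a", "b", "c"), time = 1:3,
                         event = c(1L, 1L, 1L))
  expect_error(logrank_test(surv, g_all), "two non-empty groups")
})

test_that("log-rank matches a hand-computed observed/expected table", {
  surv <- tibble::tibble(sample = c("a", "b", "c", "d"),
                         time = c(1, 2, 3, 4), event = 1L)
  g <- factor(c("A", "A", "B", "B"))
  lr <- logrank_test(surv, g)
  # O_A = 2, E_A = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9 = 17/36 -> chi2 = 49/17
  expect_equal(lr$chi2, 49 / 17, tolerance = 1e-10)
  expect_equal(lr$p, pchisq(49 / 17, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # relabelling the groups changes nothing
  g2 <- factor(c("B", "B", "A", "A"))
  expect_equal(logrank_test(surv, g2)$chi2, lr$chi2, tolerance = 1e-12)
})

test_that("identical event-time multisets give a zero statistic", {
  surv <- tibble::tibble(sample = sprintf("s%d", 1:8),
                         time = rep(c(5, 9, 13, 20), 2),
                         event = 1L)
  g <- factor(rep(c("A", "B"), each = 4))
  # same times in both groups: O = E at every event time
  surv$time <- c(5, 9, 13, 20, 5, 9, 13, 20)
  lr <- logrank_test(surv, g)
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)
})

test_that("censoring before the first event leaves the statistic unchanged", {
  surv <- tibble::tibble(sample = sprintf("s%d", 1:6),
                         time = c(3, 6, 9, 4, 8, 12),
                         event = c(1L, 1L, 0L, 1L, 1L, 0L))
  g <- factor(rep(c("A", "B"), each = 3))
  base <- logrank_test(surv, g)
  extra <- dplyr::bind_rows(surv,
                            tibble::tibble(sample = c("c1", "c2"),
                                           time = c(1, 2), event = 0L))
  g_extra <- factor(c(as.character(g), "A", "B"))
  expect_equal(logrank_test(extra, g_extra)$chi2, base$chi2,
               tolerance = 1e-12)
})

test_that("signature_survival stratifies a planted effect end to end", {
  cfg <- tiny_sim_config(seed = 44, samples_per_stage = c(100, 100, 100))
  ex <- simulate_expression(cfg)
  sig_genes <- ex$truth$lncrna[1:3]
  score <- as.numeric(scale(colMeans(ex$expr$values[sig_genes, ])))
  names(score) <- colnames(ex$expr$values)
  surv <- simulate_survival(cfg, score)
  ss <- signature_survival(ex$expr, sig_genes, surv, direction = "up",
                           set_id = "planted")
  expect_s3_class(ss, "signature_survival")
  expect_lt(glance(ss)$p, 0.01)
  td <- tidy(ss)
  expect_identical(nrow(td), 300L)
  expect_true(all(c("score", "group", "time", "event") %in% names(td)))
})
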