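test_that("spot binarization uses a strict count threshold", {
  counts <- cbind(g1 = c(0, 1, 5, 0), g2 = c(2, 2, 0, 1))
  rownames(counts) <- sprintf("sp%d", 1:4)
  expect_identical(unname(binarize_spots(counts, "g1")),
                   c(FALSE, TRUE, TRUE, FALSE))
  # raising the threshold never increases the presence count
  for (th in 0:4) {
    expect_lte(sum(binarize_spots(counts, "g2", th + 1)),
               sum(binarize_spots(counts, "g2", th)))
  }
  expect_error(binarize_spots(counts, "ghost"), "not found")
})

test_that("Fisher p-values reproduce enumerated tables and invariances", {
  # margins (5,5)/(5,5): only the two extreme tables are as improbable
  expect_equal(fisher_cooccurrence_p(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  # the modal table: every table's probability is <= the observed one
  expect_equal(fisher_cooccurrence_p(2, 2, 2, 2), 1, tolerance = 1e-12)
  # transpose invariance (swapping the two entities swaps b and c)
  expect_equal(fisher_cooccurrence_p(7, 2, 5, 11),
               fisher_cooccurrence_p(7, 5, 2, 11), tolerance = 1e-12)
  # degenerate margins are refused
  expect_error(fisher_cooccurrence_p(5, 5, 0, 0), "margin")
  expect_error(fisher_cooccurrence_p(0, 0, 3, 7), "margin")
  # one-sided option is the hypergeometric tail
  expect_equal(fisher_cooccurrence_p(5, 0, 0, 5, alternative = "greater"),
               1 / 252, tolerance = 1e-12)
})

test_that("pair calls follow the ratio and significance rule symmetrically", {
  cfg <- tiny_sim_config(seed = 19)
  sp <- simulate_spatial(cfg)
  pairs <- tibble::tibble(entity1 = sp$truth$gene1, entity2 = sp$truth$gene2)
  calls <- call_pairs(pairs, counts = sp$counts)
  expect_identical(calls$call, ifelse(sp$truth$relation == "cooccurrence",
                                      "cooccurrence", "exclusivity"))
  expect_true(all(calls$a + calls$b + calls$c + calls$d == calls$n))
  # swapping entities never changes the call
  swapped <- call_pairs(pairs[, c("entity1", "entity2")] |>
                          dplyr::rename(entity1 = "entity2",
                                        entity2 = "entity1"),
                        counts = sp$counts)
  expect_identical(swapped$call, calls$call)
  expect_equal(swapped$fisher_p, calls$fisher_p, tolerance = 1e-12)
})

test_that("the ratio is infinite when b + c = 0 and such pairs call cooccurrence", {
  counts <- cbind(g1 = c(1, 1, 0, 0, 1, 0, 1, 0, 1, 0),
                  g2 = c(1, 1, 0, 0, 1, 0, 1, 0, 1, 0))
  rownames(counts) <- sprintf("sp%02d", 1:10)
  out <- call_pairs(tibble::tibble(entity1 = "g1", entity2 = "g2"),
                    counts = counts)
  expect_identical(out$ratio, Inf)
  expect_identical(out$call, "cooccurrence")
})

test_that("cell-type entities binarize at the score median", {
  cfg <- tiny_sim_config(seed = 19)
  sp <- simulate_spatial(cfg)
  scores <- score_spot_celltypes(sp$counts, sp$markers)
  # two distinct planted cell types occupy different bands: their
  # above-median masks must differ
  p1 <- scores[, 1] > median(scores[, 1])
  expect_identical(sum(p1), sum(resolve_presence(
    colnames(scores)[1], NULL, scores, 0, 0.5)))
})

test_that("marker scores rank marker-bearing spots above empty ones", {
  set.seed(6)
  counts <- matrix(rpois(100 * 6, 0.2), 100, 6,
                   dimnames = list(sprintf("sp%03d", 1:100),
                                   c(paste0("mkA", 1:3), paste0("bg", 1:3))))
  counts[1:10, 1:3] <- counts[1:10, 1:3] + 5   # spots 1-10 express A markers
  counts[11:100, 1:3] <- 0                     # the rest express none
  markers <- tibble::tibble(cell_type = "A", gene = paste0("mkA", 1:3))
  sc <- score_spot_celltypes(counts, markers)
  expect_gt(min(sc[1:10, "A"]), max(sc[11:100, "A"]))
})

test_that("degenerate marker sets are flagged and library scaling is neutral", {
  counts <- matrix(rpois(50 * 2, 1) + 1, 50, 2,
                   dimnames = list(sprintf("sp%02d", 1:50), c("g1", "g2")))
  markers <- tibble::tibble(cell_type = c("ok", "gone"),
                            gene = c("g1", "absent"))
  expect_warning(sc <- score_spot_celltypes(counts, markers), "degenerate")
  expect_identical(attr(sc, "degenerate"), "gone")
  expect_true(all(sc[, "gone"] == 0))
  # per-spot library normalisation: a global scale factor changes nothing
  expect_warning(sc2 <- score_spot_celltypes(counts * 3L, markers))
  expect_equal(sc[, "ok"], sc2[, "ok"], tolerance = 1e-12)
})

test_that("independent background genes are mostly called none", {
  cfg <- tiny_sim_config(seed = 23)
  sp <- simulate_spatial(cfg)
  bg <- grep("^BG", colnames(sp$counts), value = TRUE)
  pairs <- tibble::tibble(entity1 = bg[c(1, 3, 5)], entity2 = bg[c(2, 4, 6)])
  calls <- call_pairs(pairs, counts = sp$counts)
  expect_gte(mean(calls$call == "none"), 2 / 3)
})
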