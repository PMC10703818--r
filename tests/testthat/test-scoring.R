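test_that("total FGS score follows the published formula", {
  expect_equal(total_fgs(c(2, 2, 2, 2, 2))$ratio, 1.0)
  expect_equal(total_fgs(c(1, 1, 1, 1, 1))$ratio, 0.5)
  s <- total_fgs(c(2, 1, 0, 2, NA))
  expect_equal(s$ratio, 5 / 8)
  expect_identical(s$n_scored, 4L)
  expect_equal(total_fgs(c(NA, NA, NA, NA, 1))$ratio, 0.5)
  expect_error(total_fgs(rep(NA, 5)), class = "felgrim_error_unscorable")
  expect_error(total_fgs(c(3, 0, 0, 0, 0)), class = "felgrim_error_config")
})

test_that("total FGS score is permutation-invariant and monotone", {
  set.seed(3)
  for (k in 1:50) {
    sc <- sample(c(0:2, NA), 5, replace = TRUE)
    if (all(is.na(sc))) sc[1] <- 1
    expect_equal(total_fgs(sample(sc))$ratio, total_fgs(sc)$ratio)
    idx <- which(!is.na(sc) & sc < 2)
    if (length(idx)) {
      i <- idx[sample.int(length(idx), 1)]
      up <- sc; up[i] <- up[i] + 1
      expect_gte(total_fgs(up)$ratio, total_fgs(sc)$ratio)
    }
  }
})

test_that("binarization is inclusive at the cut-off and monotone", {
  expect_identical(as.character(binarize_fgs(0.39, 0.39)), "painful")
  expect_identical(as.character(binarize_fgs(0.38, 0.39)), "non_painful")
  expect_identical(as.character(binarize_fgs(0, 0.2)), "non_painful")
  expect_identical(as.character(binarize_fgs(0.4, 0.4)), "painful")
  # monotone in score and in threshold
  s <- seq(0, 1, by = 0.05)
  lab <- as.integer(binarize_fgs(s, 0.4) == "painful")
  expect_true(all(diff(lab) >= 0))
  th <- seq(0, 1, by = 0.05)
  lab2 <- vapply(th, function(t) binarize_fgs(0.5, t) == "painful", logical(1))
  expect_true(all(diff(as.integer(lab2)) <= 0))
  expect_error(binarize_fgs(0.5, 1.2), class = "felgrim_error_config")
  expect_error(binarize_fgs(1.5, 0.4), class = "felgrim_error_config")
})

test_that("binary aggregation implements the AND/OR truth tables", {
  expect_identical(aggregate_binary(c(1, 1, 1), "AND"), 1L)
  expect_identical(aggregate_binary(c(1, 0, 1), "AND"), 0L)
  expect_identical(aggregate_binary(c(0, 0, 1), "OR"), 1L)
  expect_identical(aggregate_binary(c(0, 0, 0), "OR"), 0L)
  expect_identical(aggregate_binary(1, "AND"), 1L)
  expect_identical(aggregate_binary(1, "OR"), 1L)
  expect_error(aggregate_binary(integer(), "AND"), class = "felgrim_error_config")
})

test_that("continuous and ordinal aggregation match their definitions", {
  expect_equal(aggregate_continuous(c(0.2, 0.4), "mean"), 0.3)
  expect_equal(aggregate_continuous(c(0.2, 0.4, 0.1), "maximum"), 0.4)
  expect_equal(aggregate_continuous(0.7, "minimum"), 0.7)
  expect_identical(aggregate_ordinal(c(1, 1, 2), "mode"), 1L)
  expect_identical(aggregate_ordinal(c(0, 0, 2, 2), "mode"), 0L)
  expect_identical(aggregate_ordinal(c(0, 0, 2, 2), "mode", tie = "highest"), 2L)
  expect_identical(aggregate_ordinal(c(0, 2), "maximum"), 2L)
  expect_error(aggregate_ordinal(integer(), "mode"), class = "felgrim_error_config")
})

test_that("aggregation laws hold over every <=4-rater score multiset", {
  # exhaustive over all ordinal multisets of size 1..4
  for (n in 1:4) {
    combos <- as.matrix(expand.grid(rep(list(0:2), n)))
    for (r in seq_len(nrow(combos))) {
      sc <- as.integer(combos[r, ])
      mn <- aggregate_ordinal(sc, "minimum")
      mx <- aggregate_ordinal(sc, "maximum")
      md <- aggregate_ordinal(sc, "mode")
      expect_true(mn <= md && md <= mx)
      # mode equals the independent tabulate-then-lowest-tie oracle
      tab <- table(factor(sc, levels = 0:2))
      oracle <- min(as.integer(names(tab)[tab == max(tab)]))
      expect_identical(md, oracle)
      # ratios: min <= mean <= max
      ratio <- sc / 2
      expect_true(aggregate_continuous(ratio, "minimum") <=
                    aggregate_continuous(ratio, "mean"))
      expect_true(aggregate_continuous(ratio, "mean") <=
                    aggregate_continuous(ratio, "maximum"))
      # binary: AND <= OR; identical values aggregate to themselves
      bin <- as.integer(sc > 0)
      expect_lte(aggregate_binary(bin, "AND"), aggregate_binary(bin, "OR"))
      expect_identical(aggregate_binary(rep(1L, n), "AND"), 1L)
      expect_identical(aggregate_ordinal(rep(sc[1], n), "mode"), sc[1])
    }
  }
})

test_that("rater tables score and aggregate tidily", {
  raters <- tibble::tibble(
    image_id = rep(c("i1", "i2"), each = 2),
    rater_id = rep(c("r1", "r2"), 2),
    ear_position = c(2, 2, 0, 0),
    orbital_tightening = c(2, 1, 0, 1),
    muzzle_tension = c(2, 2, 0, 0),
    whiskers_change = c(2, 2, NA, 0),
    head_position = c(2, 2, 0, 0)
  )
  scored <- score_raters(raters, threshold = 0.4)
  expect_equal(scored$ratio, c(1, 0.9, 0, 0.1))
  expect_identical(scored$n_scored, c(5L, 5L, 4L, 5L))
  expect_identical(scored$painful, c(1L, 1L, 0L, 0L))
  lab <- aggregate_raters(scored, "binary", "AND")
  expect_identical(lab$label, c(1L, 0L))
  cont <- aggregate_raters(scored, "continuous", "mean")
  expect_equal(cont$score, c(0.95, 0.05))
  ord <- aggregate_raters(raters, "ordinal", "mode")
  expect_identical(ord$orbital_tightening, c(1L, 0L))
})
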