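test_that("weighted_normalized reproduces the published ideal vectors", {
  p <- china_mch("raw")
  w <- entropy_weights(p)$weights
  wm <- weighted_normalized(p, w)
  expect_lt(max(abs(apply(wm, 2, max) - ref_ideal)), 0.0005)
  expect_lt(max(abs(apply(wm, 2, min) - ref_anti_ideal)), 0.0005)
  expect_error(weighted_normalized(p, w[-1]), "length")
  expect_error(weighted_normalized(p, w * 2), "sum to 1")
})

test_that("single-row normalization degenerates to the weights", {
  # each column of a 1-row panel normalizes to 1, so the row equals W
  w <- c(0.3, 0.7)
  vals <- matrix(c(4, 4, 9, 9), 2, 2)  # duplicated row keeps n >= 2
  p <- indicator_panel(vals, rep("benefit", 2))
  wm <- weighted_normalized(p, w)
  expect_equal(unname(wm[1, ]), w / sqrt(2))
})

test_that("distances and closeness behave at the extremes", {
  wm <- matrix(c(0, 1, 0.5, 0, 1, 0.5), 3, 2)
  ideal <- apply(wm, 2, max); anti <- apply(wm, 2, min)
  d <- topsis_distances(wm, ideal, anti)
  expect_equal(d$d_plus[2], 0)          # the ideal row
  expect_equal(d$d_minus[1], 0)         # the anti-ideal row
  expect_equal(closeness(0, 3), 1.0)
  expect_equal(closeness(3, 0), 0.0)
  # 1-column case reduces to absolute differences
  one <- matrix(c(2, 5, 3), 3, 1)
  d1 <- topsis_distances(one, 5, 2)
  expect_equal(d1$d_plus, c(3, 0, 2))
  expect_equal(d1$d_minus, c(0, 3, 1))
  expect_warning(closeness(0, 0), "0.5")
})

test_that("closeness matches a brute-force oracle on random matrices", {
  set.seed(33)
  for (i in 1:5) {
    wm <- matrix(stats::runif(32), 8, 4)
    ideal <- apply(wm, 2, max); anti <- apply(wm, 2, min)
    d <- topsis_distances(wm, ideal, anti)
    C <- closeness(d$d_plus, d$d_minus)
    for (r in 1:8) {
      dp <- dm <- 0
      for (j in 1:4) {
        dp <- dp + (ideal[j] - wm[r, j])^2
        dm <- dm + (anti[j] - wm[r, j])^2
      }
      expect_equal(C[r], sqrt(dm) / (sqrt(dp) + sqrt(dm)), tolerance = 1e-12)
    }
  }
})

test_that("rank_desc ranks descending with first-occurrence ties", {
  expect_equal(rank_desc(c(0.1, 0.5, 0.3)), c(3L, 1L, 2L))
  expect_equal(rank_desc(1:5), 5:1)
  expect_equal(rank_desc(rep(2, 4)), 1:4)
  expect_equal(rank_desc(c(1, 3, 3, 2)), c(4L, 1L, 2L, 3L))
})

test_that("topsis on the China panel recovers the published rank order", {
  res <- topsis(china_mch("raw"))
  expect_equal(unname(round(res$d_plus, 4)), ref_d_plus)
  expect_equal(unname(res$ranks), ref_topsis_ranks)
  expect_equal(unname(round(res$closeness["2004"], 4)), 0.0042)
  expect_equal(unname(round(res$closeness["2006"], 4)), 0.1025)
  expect_true(all(res$closeness >= 0 & res$closeness <= 1))
  expect_true(all(res$d_plus >= 0 & res$d_minus >= 0))
  expect_equal(sort(unname(res$ranks)), 1:15)
})

test_that("difference co-trend is selectable and changes only cost columns", {
  p <- china_mch("raw")
  w <- entropy_weights(p)$weights
  recip <- weighted_normalized(p, w, "reciprocal")
  diffs <- weighted_normalized(p, w, "difference")
  expect_equal(recip[, 2:6], diffs[, 2:6])
  expect_false(isTRUE(all.equal(recip[, 1], diffs[, 1])))
  # difference co-trend makes the mortality column almost constant
  expect_equal(unname(diffs[, 1] / w[["X1"]]), rep(1 / sqrt(15), 15),
               tolerance = 1e-3)
})

test_that("closeness is monotone under dominance and scale-invariant", {
  set.seed(7)
  for (i in 1:5) {
    # monotone panel: later rows dominate earlier ones componentwise
    vals <- apply(matrix(stats::runif(10 * 3, 0.5, 2), 10, 3), 2, cumsum)
    rownames(vals) <- paste0("a", 1:10)
    p <- indicator_panel(vals, rep("benefit", 3))
    w <- c(0.2, 0.5, 0.3)
    C <- topsis(p, w)$closeness
    expect_true(all(diff(C) > 0), info = sprintf("draw %d", i))
    # rescaling a raw column leaves closeness unchanged
    vals2 <- vals; vals2[, 2] <- vals2[, 2] * 37
    p2 <- indicator_panel(vals2, rep("benefit", 3))
    expect_equal(topsis(p2, w)$closeness, C)
  }
})
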