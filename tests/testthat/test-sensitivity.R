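test_that("gamma_from_beta evaluates the change-rate formula", {
  expect_equal(gamma_from_beta(1, 0.3), 1.0)
  w <- 0.1154
  expect_equal(gamma_from_beta(4.5, w),
               (4.5 - 4.5 * w) / (1 - 4.5 * w), tolerance = 1e-12)
  expect_equal(round(gamma_from_beta(4.5, w), 4), 8.2810)
  expect_equal(round(gamma_from_beta(0.01, w), 6), 0.008856)
  expect_error(gamma_from_beta(10, 0.2), ">= 1")
  expect_error(gamma_from_beta(-1, 0.2), "positive")
  expect_error(gamma_from_beta(1, 1.2), "between 0 and 1")
})

test_that("perturb_weights reproduces the published weight table", {
  w <- entropy_weights(china_mch("raw"))$weights
  got <- t(vapply(ref_beta_grid, function(b) perturb_weights(w, 1, b),
                  numeric(6)))
  # all published rows except the mislabelled beta = 0.5 one (see helper)
  expect_lt(max(abs(got[ref_beta_ok_rows, ] -
                    ref_perturbed_weights[ref_beta_ok_rows, ])), 0.0005)
  # the beta = 0.5 row is exactly the published beta = 0.4 computation
  expect_lt(max(abs(perturb_weights(w, 1, 0.4) -
                    ref_perturbed_weights[6, ])), 0.0005)
  expect_equal(unname(perturb_weights(w, 1, 1)), unname(w))
  expect_error(perturb_weights(c(0.5, 0.6), 1, 2), "sum to 1")
})

test_that("perturbation identities hold across the grid for every k", {
  w <- entropy_weights(china_mch("raw"))$weights
  for (k in 1:6) {
    for (b in ref_beta_grid) {
      if (b * w[[k]] >= 1) next
      wp <- perturb_weights(w, k, b)
      expect_equal(sum(wp), 1, tolerance = 1e-12)
      expect_true(all(wp >= 0))
      # the defining identity of the unitary variation rate
      expect_equal(wp[[k]], b * w[[k]], tolerance = 1e-12)
      # unperturbed weights keep their pairwise ratios
      others <- setdiff(1:6, k)
      expect_equal(wp[others] / wp[others[1]], w[others] / w[others[1]],
                   tolerance = 1e-12)
    }
  }
})

test_that("sensitivity_sweep recomputes closeness under each scheme", {
  p <- china_mch("raw")
  base <- topsis(p)
  sw <- sensitivity_sweep(p, k = 1, betas = c(1))
  expect_equal(unname(sw$closeness_matrix[1, ]), unname(base$closeness))
  expect_equal(unname(sw$rank_matrix[1, ]), as.numeric(base$ranks))

  sw14 <- sensitivity_sweep(p, k = 1)
  expect_equal(dim(sw14$weight_vectors), c(14L, 6L))
  expect_lt(max(abs(sw14$weight_vectors[ref_beta_ok_rows, ] -
                    ref_perturbed_weights[ref_beta_ok_rows, ])), 0.0005)
  expect_equal(sw14$gammas[7], 1)  # beta = 1 entry
  expect_error(sensitivity_sweep(p, k = 3, betas = c(5)), "invalid beta")
  expect_error(sensitivity_sweep(p, k = 9), "does not identify")
})

test_that("the beta -> 0 limit hands the ranking to the other indicator", {
  vals <- matrix(c(1, 2, 3,
                   30, 10, 20), 3, 2,
                 dimnames = list(c("a", "b", "c"), c("u", "v")))
  p <- indicator_panel(vals, c(u = "benefit", v = "benefit"))
  sw <- sensitivity_sweep(p, weights = c(0.5, 0.5), k = 1,
                          betas = c(1e-6))
  solo <- topsis(indicator_panel(vals[, 2, drop = FALSE],
                                 c(v = "benefit")), weights = 1)
  expect_equal(unname(sw$rank_matrix[1, ]), as.numeric(solo$ranks))
})

test_that("rank_crossings finds order changes with bracketing intervals", {
  p <- china_mch("raw")
  # indicator 6 never disturbs the ranking
  expect_equal(nrow(rank_crossings(sensitivity_sweep(p, k = 6))), 0L)
  # indicator 1 does
  cr <- rank_crossings(sensitivity_sweep(p, k = 1))
  expect_gt(nrow(cr), 0L)
  expect_true(all(cr$beta_lower < cr$beta_upper))
  expect_true(all(cr$beta_lower %in% ref_beta_grid))
  sw1 <- sensitivity_sweep(p, k = 1, betas = c(1))
  expect_error(rank_crossings(sw1), "at least 2")
})
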