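test_that("run_config validates and read_run_config resolves paths", {
  expect_error(run_config(china_mch(), ratio_schemes = list(c(0.5, 0.6))),
               "summing to 1")
  expect_error(run_config(china_mch(), digits = -1), "digits")
  expect_error(run_config("no/file.csv", "s.json"), "does not exist")
  expect_error(run_config("no/file.csv"), "does not exist")

  dir <- withr::local_tempdir()
  write_panel(china_mch(), file.path(dir, "panel.csv"))
  write_schema(china_mch(), file.path(dir, "schema.json"))
  writeLines(
    '{"panel": "panel.csv", "schema": "schema.json", "digits": 3,
      "betas": [0.5, 1, 2], "ratio_schemes": [[0.2, 0.8], [0.5, 0.5]]}',
    file.path(dir, "config.json"))
  cfg <- read_run_config(file.path(dir, "config.json"))
  expect_equal(cfg$digits, 3)
  expect_equal(cfg$betas, c(0.5, 1, 2))
  expect_equal(length(cfg$ratio_schemes), 2L)
  expect_s3_class(run_evaluate(cfg, quiet = TRUE)$panel, "indicator_panel")
})

test_that("run_evaluate writes the five stage tables plus summary", {
  out <- withr::local_tempdir()
  res <- run_evaluate(run_config(china_mch(), out = out), quiet = TRUE)
  for (f in c("weights.csv", "topsis.csv", "wrsr.csv", "fuzzy.csv",
              "concordance.csv", "summary.json",
              "weights_full.csv", "topsis_full.csv"))
    expect_true(file.exists(file.path(out, f)), info = f)
  wtab <- utils::read.csv(file.path(out, "weights.csv"))
  expect_equal(wtab$weight, ref_weights)
  smry <- jsonlite::read_json(file.path(out, "summary.json"),
                              simplifyVector = TRUE)
  expect_equal(smry$n_alternatives, 15)
  expect_equal(unname(unlist(smry$topsis_ranks)), 15:1)
  # two runs on the same inputs are byte-identical
  out2 <- withr::local_tempdir()
  run_evaluate(run_config(china_mch(), out = out2), quiet = TRUE)
  for (f in c("topsis.csv", "fuzzy.csv"))
    expect_identical(readLines(file.path(out, f)),
                     readLines(file.path(out2, f)))
})

test_that("run_evaluate on a single-indicator panel degenerates sanely", {
  vals <- matrix(c(3, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "only"))
  p <- indicator_panel(vals, c(only = "benefit"))
  res <- run_evaluate(run_config(p, out = withr::local_tempdir()),
                      quiet = TRUE)
  expect_equal(unname(res$weights$weights), 1)
  expect_equal(unname(res$topsis$ranks), unname(res$wrsr$ranks))
})

test_that("zero-noise synthetic config yields generation-order tables", {
  ind <- default_synthetic_indicators()
  ind$noise <- 0; ind$tie_prob <- 0
  p <- generate_panel(synthetic_spec(n_alternatives = 8, indicators = ind))
  res <- run_evaluate(run_config(p, out = withr::local_tempdir()),
                      quiet = TRUE)
  expect_equal(unname(res$topsis$ranks), 8:1)
  expect_equal(unname(res$wrsr$ranks), 8:1)
  expect_equal(unname(res$fuzzy$comprehensive_rank), 8:1)
})

test_that("stage failures abort with a stage name and clean up", {
  out <- withr::local_tempdir()
  flat <- indicator_panel(matrix(5, 3, 2), rep("benefit", 2))
  expect_error(run_evaluate(run_config(flat, out = out), quiet = TRUE),
               "stage 'entropy_weights'")
  expect_equal(length(list.files(out, pattern = "\\.csv$")), 0L)
})

test_that("run_sensitivity writes per-indicator sweep files", {
  out <- withr::local_tempdir()
  cfg <- run_config(china_mch(), out = out, betas = c(0.5, 1, 2))
  sweeps <- run_sensitivity(cfg, k = 1, quiet = TRUE)
  expect_named(sweeps, "X1")
  expect_true(file.exists(file.path(out, "sensitivity_weights_k1.csv")))
  expect_true(file.exists(file.path(out, "sensitivity_long_k1.csv")))
  long <- utils::read.csv(file.path(out, "sensitivity_long_k1.csv"))
  expect_equal(nrow(long), 3 * 15)
  all_sweeps <- run_sensitivity(cfg, k = "all", quiet = TRUE)
  expect_equal(length(all_sweeps), 6L)
  expect_equal(length(list.files(out, pattern = "sensitivity_weights")), 6L)
  # beta = 1 row of the sweep equals the baseline closeness
  base <- topsis(china_mch())
  expect_equal(unname(all_sweeps[["X3"]]$closeness_matrix[2, ]),
               unname(base$closeness))
})
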