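# Shared fixtures and frozen reference values.

# tiny all-benefit panel with a strict dominance ordering (row 3 dominates)
tiny_benefit_panel <- function() {
  indicator_panel(
    matrix(c(1, 2, 3,
             10, 20, 30), nrow = 3,
           dimnames = list(c("a", "b", "c"), c("I1", "I2"))),
    directions = c(I1 = "benefit", I2 = "benefit"))
}

# mixed-direction 4x3 panel with a tie in the cost column
mixed_panel <- function() {
  indicator_panel(
    matrix(c(5, 4, 4, 2,
             1, 3, 2, 4,
             10, 30, 20, 40), nrow = 4,
           dimnames = list(paste0("r", 1:4), c("C1", "B1", "B2"))),
    directions = c(C1 = "cost", B1 = "benefit", B2 = "benefit"),
    cost_reference = c(C1 = 100))
}

# random positive panel generator for property-style loops
random_panel <- function(n, m, seed) {
  set.seed(seed)
  vals <- matrix(stats::runif(n * m, 1, 100), n, m,
                 dimnames = list(paste0("a", seq_len(n)),
                                 paste0("x", seq_len(m))))
  dirs <- sample(c("benefit", "cost"), m, replace = TRUE)
  indicator_panel(vals, stats::setNames(dirs, colnames(vals)))
}

# Published reference values for the bundled 2004-2018 panel -----------------

ref_entropies <- c(0.9285, 0.8769, 0.8649, 0.8801, 0.8801, 0.9498)
ref_weights <- c(0.1154, 0.1986, 0.2180, 0.1935, 0.1935, 0.0809)
ref_ideal <- c(0.0417, 0.0534, 0.0610, 0.0515, 0.0521, 0.0218)
ref_anti_ideal <- c(0.0158, 0.0488, 0.0509, 0.0479, 0.0472, 0.0181)

ref_d_plus <- c(0.0291, 0.0287, 0.0265, 0.0239, 0.0224, 0.0198, 0.0173,
                0.0135, 0.0110, 0.0090, 0.0067, 0.0037, 0.0034, 0.0031,
                0.0026)
ref_closeness <- c(0.0042, 0.0917, 0.1025, 0.2394, 0.2923, 0.3955, 0.4926,
                   0.5932, 0.6741, 0.7368, 0.8029, 0.8888, 0.9002, 0.9066,
                   0.9253)
ref_topsis_ranks <- 15:1

ref_wrsr <- c(0.0993, 0.1869, 0.1138, 0.2733, 0.3267, 0.4000, 0.4928,
              0.5336, 0.6132, 0.6798, 0.7885, 0.8745, 0.9607, 0.8667,
              0.7896)
ref_wrsr_ranks <- c(15, 13, 14, 12, 11, 10, 9, 8, 7, 6, 5, 2, 1, 3, 4)
ref_rank_matrix <- matrix(c(
  1,    2,  1,  1.5,  2,  1,
  2,    3,  3,  3,    3,  2,
  3,    1,  2,  1.5,  1,  3,
  4,  4.5,  4,  4,    4,  4,
  5,  4.5,  5,  5,    5,  5,
  6,    6,  6,  6,    6,  6,
  7,    8,  7,  8,    7,  7,
  8,    9,  8,  7,    8,  8,
  9,   10,  9,  9,    9,  9,
  10,  11, 10, 10,   10, 10,
  11,  12, 13, 11,   12, 11,
  12,  13, 14, 12.5, 14, 12,
  13, 14.5, 15, 14.5, 15, 13,
  14, 14.5, 11, 12.5, 13, 14.5,
  15,   7, 12, 14.5, 11, 14.5), nrow = 15, byrow = TRUE)

ref_fuzzy_scores <- matrix(c(   # columns: (0.1,0.9), (0.5,0.5), (0.9,0.1)
  0.0898, 0.0521, 0.0144,
  0.1720, 0.1124, 0.0528,
  0.1128, 0.1090, 0.1051,
  0.2666, 0.2400, 0.2134,
  0.3206, 0.2961, 0.2717,
  0.3990, 0.3954, 0.3918,
  0.4957, 0.5072, 0.5188,
  0.5420, 0.5756, 0.6091,
  0.6228, 0.6614, 0.7000,
  0.6891, 0.7261, 0.7631,
  0.7928, 0.8102, 0.8276,
  0.8778, 0.8912, 0.9047,
  0.9564, 0.9394, 0.9224,
  0.8722, 0.8940, 0.9158,
  0.8037, 0.8602, 0.9167), nrow = 15, byrow = TRUE)
ref_comprehensive_ranks <- c(15, 13, 14, 12, 11, 10, 9, 8, 7, 6, 5, 3, 1,
                             2, 4)

ref_rho <- c(0.964, 0.971, 0.996)

ref_beta_grid <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 1.5, 2, 2.5, 3,
                   3.5, 4, 4.5)
# The published row labelled beta = 0.5 actually corresponds to beta = 0.4
# (its first entry 0.0462 = 0.4 * 0.1154, and the remaining entries match
# beta = 0.4 too); the correctly computed beta = 0.5 row differs. Row 6 is
# therefore excluded from the green comparisons and asserted red in the
# acceptance suite.
ref_beta_ok_rows <- setdiff(1:14, 6)
ref_perturbed_weights <- matrix(c(
  0.0012, 0.2243, 0.2462, 0.2185, 0.2185, 0.0914,
  0.0023, 0.2240, 0.2459, 0.2183, 0.2183, 0.0913,
  0.0058, 0.2232, 0.2450, 0.2175, 0.2175, 0.0909,
  0.0115, 0.2219, 0.2436, 0.2162, 0.2162, 0.0904,
  0.0231, 0.2194, 0.2408, 0.2137, 0.2137, 0.0894,
  0.0462, 0.2142, 0.2351, 0.2087, 0.2087, 0.0872,
  0.1154, 0.1986, 0.2180, 0.1935, 0.1935, 0.0809,
  0.1731, 0.1857, 0.2038, 0.1809, 0.1809, 0.0756,
  0.2308, 0.1727, 0.1896, 0.1683, 0.1683, 0.0704,
  0.2885, 0.1597, 0.1754, 0.1556, 0.1556, 0.0651,
  0.3462, 0.1468, 0.1611, 0.1430, 0.1430, 0.0598,
  0.4039, 0.1338, 0.1469, 0.1304, 0.1304, 0.0545,
  0.4616, 0.1209, 0.1327, 0.1178, 0.1178, 0.0492,
  0.5193, 0.1079, 0.1185, 0.1052, 0.1052, 0.0440), nrow = 14, byrow = TRUE)
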