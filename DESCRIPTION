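Package: mcdaeval
Title: Entropy-Weighted Multi-Criteria Evaluation of Indicator Panels
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrated multi-criteria decision analysis (MCDA) for rectangular
    alternatives-by-indicators panels, such as yearly health-service indicator
    tables. Computes objective indicator weights by the entropy weight method,
    ranks alternatives by weighted TOPSIS (closeness to the ideal solution) and
    by the weighted rank-sum ratio (WRSR) with midrank tie handling, combines
    the two scores by fuzzy convex combination with a modal comprehensive rank,
    measures cross-method concordance by Spearman rank correlation, and probes
    ranking stability with a weight-perturbation sensitivity sweep. Includes a
    seeded synthetic panel generator, CSV/JSON panel I/O, and report emission.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
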