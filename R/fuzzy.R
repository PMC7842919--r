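#' Fuzzy convex combination of two scores
#'
#' `W1 * closeness + W2 * wrsr`, elementwise, with `W1 + W2 = 1`. The
#' combination is monotone in both arguments and always lies between the
#' two input scores.
#'
#' @param closeness n-vector of TOPSIS closeness coefficients.
#' @param wrsr n-vector of WRSR scores.
#' @param ratio numeric pair `(W1, W2)`, both non-negative, summing to 1;
#'   `W1` multiplies the closeness coefficient.
#' @return n-vector of combined scores.
#' @export
fuzzy_combine <- function(closeness, wrsr, ratio) {
  if (length(ratio) != 2L || any(ratio < 0) || abs(sum(ratio) - 1) > 1e-8)
    stop("ratio must be a non-negative pair (W1, W2) summing to 1",
         call. = FALSE)
  if (length(closeness) != length(wrsr))
    stop("closeness and wrsr must have equal length", call. = FALSE)
  ratio[[1L]] * closeness + ratio[[2L]] * wrsr
}

#' Modal comprehensive rank across ratio schemes
#'
#' For each alternative, the rank that occurs most often across the scheme
#' rankings. When no strict mode exists (all scheme ranks distinct), the
#' rank under the balanced scheme is used as tie-break.
#'
#' @param scheme_ranks n x k matrix of per-scheme ranks.
#' @param fallback column index of the balanced scheme used when no strict
#'   mode exists.
#' @return n-vector of comprehensive ranks.
#' @export
comprehensive_rank <- function(scheme_ranks, fallback = 1L) {
  apply(scheme_ranks, 1L, function(r) {
    tab <- table(r)
    top <- tab[tab == max(tab)]
    if (max(tab) > 1L && length(top) == 1L) as.numeric(names(top))
    else r[[fallback]]
  })
}

#' Fuzzy comprehensive evaluation
#'
#' Combines the TOPSIS closeness coefficient and the WRSR score under
#' several weight-ratio schemes (default `0.1:0.9`, `0.5:0.5`, `0.9:0.1`,
#' with the first weight on the closeness coefficient), ranks each scheme's
#' scores, and summarizes by the modal rank across schemes
#' ([comprehensive_rank()]). The extreme schemes `(1, 0)` and `(0, 1)`
#' recover the pure TOPSIS and pure WRSR rankings.
#'
#' @inheritParams fuzzy_combine
#' @param schemes list of `(W1, W2)` pairs.
#' @return an object of class `fuzzy_result`: list with `ratio_schemes`,
#'   `scores` (n x k), `scheme_ranks` (n x k), `comprehensive_rank`.
#' @examples
#' ts <- topsis(china_mch()); rs <- wrsr(china_mch())
#' fz <- fuzzy_evaluate(ts$closeness, rs$wrsr)
#' fz$comprehensive_rank[c("2004", "2016")]
#' @export
fuzzy_evaluate <- function(closeness, wrsr,
                           schemes = list(c(0.1, 0.9), c(0.5, 0.5),
                                          c(0.9, 0.1))) {
  if (!length(schemes))
    stop("at least one ratio scheme is required", call. = FALSE)
  labs <- vapply(schemes, function(s) sprintf("%g:%g", s[1L], s[2L]),
                 character(1L))
  scores <- vapply(schemes, function(s) fuzzy_combine(closeness, wrsr, s),
                   numeric(length(closeness)))
  ranks <- apply(scores, 2L, rank_desc)
  dimnames(scores) <- dimnames(ranks) <- list(names(closeness), labs)
  # balanced scheme = the one closest to (0.5, 0.5)
  w1 <- vapply(schemes, `[[`, numeric(1L), 1L)
  fallback <- which.min(abs(w1 - 0.5))
  structure(list(ratio_schemes = schemes, scores = scores,
                 scheme_ranks = ranks,
                 comprehensive_rank = stats::setNames(
                   comprehensive_rank(ranks, fallback), names(closeness))),
            class = "fuzzy_result")
}

#' @export
print.fuzzy_result <- function(x, digits = 4, ...) {
  cat("fuzzy comprehensive evaluation\n")
  df <- data.frame(round(x$scores, digits), check.names = FALSE)
  df$comprehensive <- x$comprehensive_rank
  print(df)
  invisible(x)
}

#' Write a fuzzy evaluation table (CSV)
#'
#' One row per alternative: score and rank per scheme, plus the
#' comprehensive ranking.
#'
#' @param res a [fuzzy_evaluate()] result.
#' @param path output CSV path.
#' @param digits rounding for display values; `NA` writes full precision.
#' @return `path`, invisibly.
#' @export
write_fuzzy_table <- function(res, path, digits = 4) {
  df <- data.frame(alternative = rownames(res$scores), row.names = NULL)
  for (lab in colnames(res$scores)) {
    s <- res$scores[, lab]
    df[[paste0("score_", lab)]] <- if (is.na(digits)) s else round(s, digits)
    df[[paste0("rank_", lab)]] <- res$scheme_ranks[, lab]
  }
  df$comprehensive_rank <- res$comprehensive_rank
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
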