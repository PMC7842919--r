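#' Spearman rank concordance between two method rankings
#'
#' Without ties the classical shortcut `rho = 1 - 6 * sum(d^2) / (n (n^2 - 1))`
#' is used, where `d` is the vector of rank differences. With ties the
#' shortcut is no longer exact and the product-moment correlation of
#' midranks is used instead. The p-value comes from the t-approximation
#' with `n - 2` degrees of freedom.
#'
#' @param ranks_a,ranks_b numeric rank vectors of equal length `n >= 3`.
#'   Arbitrary scores are accepted and converted to midranks.
#' @param method_pair optional character pair labelling the two methods.
#' @return an object of class `concordance`: list with `method_pair`,
#'   `rho`, `sum_d2` (sum of squared rank differences), `p_value`, `n`.
#' @examples
#' ts <- topsis(china_mch()); rs <- wrsr(china_mch())
#' spearman_concordance(ts$ranks, rs$ranks, c("TOPSIS", "WRSR"))
#' @export
spearman_concordance <- function(ranks_a, ranks_b,
                                 method_pair = c("a", "b")) {
  n <- length(ranks_a)
  if (length(ranks_b) != n)
    stop("rank vectors must have equal length", call. = FALSE)
  if (n < 3L)
    stop("at least 3 paired ranks are required", call. = FALSE)
  ra <- rank(ranks_a, ties.method = "average")
  rb <- rank(ranks_b, ties.method = "average")
  if (stats::var(ra) == 0 || stats::var(rb) == 0)
    stop("constant rank vector: Spearman correlation undefined",
         call. = FALSE)
  sum_d2 <- sum((ra - rb)^2)
  has_ties <- anyDuplicated(ra) || anyDuplicated(rb)
  rho <- if (has_ties) stats::cor(ra, rb)  # midrank product-moment form
         else 1 - 6 * sum_d2 / (n * (n^2 - 1))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(method_pair = method_pair, rho = rho, sum_d2 = sum_d2,
                 p_value = p, n = n),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Spearman concordance %s vs %s: rho = %.3f (p = %.2g, n = %d)\n",
              x$method_pair[1L], x$method_pair[2L], x$rho, x$p_value, x$n))
  invisible(x)
}

#' Pairwise concordance table for the standard method trio
#'
#' Convenience wrapper computing the three Spearman correlations between
#' the TOPSIS, WRSR, and balanced fuzzy-combination rankings.
#'
#' @param topsis_ranks,wrsr_ranks,fuzzy_ranks rank vectors (1 = best).
#' @return data frame with one row per pair: `pair`, `rho`, `sum_d2`, `p`.
#' @export
concordance_table <- function(topsis_ranks, wrsr_ranks, fuzzy_ranks) {
  pairs <- list(
    list(a = topsis_ranks, b = wrsr_ranks, lab = c("TOPSIS", "WRSR")),
    list(a = topsis_ranks, b = fuzzy_ranks, lab = c("TOPSIS", "fuzzy")),
    list(a = wrsr_ranks, b = fuzzy_ranks, lab = c("WRSR", "fuzzy")))
  do.call(rbind, lapply(pairs, function(p) {
    cc <- spearman_concordance(p$a, p$b, p$lab)
    data.frame(pair = paste(p$lab, collapse = " vs "), rho = cc$rho,
               sum_d2 = cc$sum_d2, p = cc$p_value)
  }))
}
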