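#' Midranks of one indicator column
#'
#' Ranks a column across alternatives so that rank `n` is best: benefit
#' indicators ascending (largest value gets rank `n`), cost indicators
#' descending (smallest value gets rank `n`). Exact ties receive the
#' arithmetic mean of their positional ranks (midranks), which is why
#' half-integer ranks appear.
#'
#' @param values numeric vector.
#' @param direction `"benefit"` or `"cost"`.
#' @return numeric rank vector; always sums to `n(n+1)/2`.
#' @export
midrank_column <- function(values, direction = c("benefit", "cost")) {
  direction <- match.arg(direction)
  if (direction == "benefit") rank(values, ties.method = "average")
  else rank(-values, ties.method = "average")
}

#' Rank-sum ratio scores
#'
#' `RSR_i = sum_j(R_ij) / (m * n)`: the unweighted rank-sum ratio, in
#' `(0, 1]`.
#'
#' @param rank_matrix n x m matrix of midranks.
#' @return n-vector of RSR scores.
#' @export
rsr_scores <- function(rank_matrix) {
  rowSums(rank_matrix) / (ncol(rank_matrix) * nrow(rank_matrix))
}

#' Weighted rank-sum ratio scores
#'
#' `WRSR_i = sum_j(W_j * R_ij) / n`; larger is better. With equal weights
#' `1/m` this reduces to [rsr_scores()].
#'
#' @param rank_matrix n x m matrix of midranks.
#' @param weights m-vector of indicator weights summing to 1.
#' @return n-vector of WRSR scores in `(0, 1]`.
#' @export
wrsr_scores <- function(rank_matrix, weights) {
  if (length(weights) != ncol(rank_matrix))
    stop("weights length does not match the number of indicators",
         call. = FALSE)
  as.vector(rank_matrix %*% weights) / nrow(rank_matrix)
}

#' Weighted rank-sum ratio evaluation
#'
#' Replaces each indicator column by within-column midranks (best = `n`),
#' then scores each alternative by the weighted mean rank divided by `n`.
#' Being rank-based, the result is invariant under any strictly monotone
#' transform of a raw column and robust to outliers.
#'
#' @param panel an [indicator_panel()].
#' @param weights indicator weights; defaults to [entropy_weights()] of the
#'   panel.
#' @return an object of class `rsr_result`: list with `rank_matrix`, `rsr`,
#'   `wrsr`, `ranks` (1 = best), and `weights`.
#' @examples
#' res <- wrsr(china_mch())
#' round(res$wrsr[c("2004", "2016")], 4)
#' @export
wrsr <- function(panel, weights = NULL) {
  stopifnot(inherits(panel, "indicator_panel"))
  if (is.null(weights)) weights <- entropy_weights(panel)$weights
  X <- panel$values
  R <- X
  for (j in seq_len(ncol(X)))
    R[, j] <- midrank_column(X[, j], panel$directions[[j]])
  w <- wrsr_scores(R, weights)
  structure(list(rank_matrix = R,
                 rsr = stats::setNames(rsr_scores(R), rownames(X)),
                 wrsr = stats::setNames(w, rownames(X)),
                 ranks = stats::setNames(rank_desc(w), rownames(X)),
                 weights = weights),
            class = "rsr_result")
}

#' @export
print.rsr_result <- function(x, digits = 4, ...) {
  cat("weighted rank-sum ratio (WRSR)\n")
  print(data.frame(wrsr = round(x$wrsr, digits), rank = x$ranks))
  invisible(x)
}

#' Write a WRSR result table (CSV)
#'
#' One row per alternative: each indicator's value and midrank, WRSR, rank.
#'
#' @param panel the evaluated [indicator_panel()].
#' @param res a [wrsr()] result on that panel.
#' @param path output CSV path.
#' @param digits rounding for display values; `NA` writes full precision.
#' @return `path`, invisibly.
#' @export
write_wrsr_table <- function(panel, res, path, digits = 4) {
  X <- panel$values
  df <- data.frame(alternative = rownames(X), row.names = NULL)
  for (j in colnames(X)) {
    df[[j]] <- X[, j]
    df[[paste0(j, "_rank")]] <- res$rank_matrix[, j]
  }
  df$wrsr <- if (is.na(digits)) res$wrsr else round(res$wrsr, digits)
  df$rank <- res$ranks
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
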