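#' Weighted, vector-normalized decision matrix
#'
#' Builds the matrix on which TOPSIS distances are computed: each cost
#' column is first co-trended (reciprocal by default, or difference against
#' the panel's `cost_reference`), every column is then divided by its
#' Euclidean norm ([vector_normalize()]) and multiplied by its weight.
#'
#' @param panel an [indicator_panel()].
#' @param weights m-vector of indicator weights summing to 1.
#' @param cotrend co-trend method for cost indicators: a single string
#'   (`"reciprocal"` or `"difference"`) applied to all cost columns, or a
#'   named character vector per cost indicator.
#' @return n x m matrix; column maxima form the ideal solution `A+`, column
#'   minima the anti-ideal `A-`.
#' @export
weighted_normalized <- function(panel, weights, cotrend = "reciprocal") {
  stopifnot(inherits(panel, "indicator_panel"))
  X <- panel$values
  m <- ncol(X)
  if (length(weights) != m)
    stop("weights length does not match the number of indicators",
         call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1", call. = FALSE)
  methods <- if (is.null(names(cotrend)))
    stats::setNames(rep(cotrend[[1L]], m), colnames(X))
  else {
    full <- stats::setNames(rep("reciprocal", m), colnames(X))
    full[names(cotrend)] <- cotrend
    full
  }
  out <- X
  for (j in seq_len(m)) {
    col <- X[, j]
    if (panel$directions[[j]] == "cost") {
      cfg <- if (methods[[j]] == "difference")
        cotrend_config("difference", panel$cost_reference[[j]])
      else cotrend_config("reciprocal")
      col <- cotrend_column(col, cfg)
    }
    out[, j] <- vector_normalize(col) * weights[[j]]
  }
  out
}

#' Euclidean distances to the ideal and anti-ideal solutions
#'
#' @param weighted n x m weighted normalized matrix.
#' @param ideal m-vector `A+` (componentwise column maxima).
#' @param anti_ideal m-vector `A-` (componentwise column minima).
#' @return list with numeric n-vectors `d_plus` and `d_minus`.
#' @export
topsis_distances <- function(weighted, ideal, anti_ideal) {
  stopifnot(ncol(weighted) == length(ideal),
            ncol(weighted) == length(anti_ideal))
  list(d_plus  = sqrt(rowSums(sweep(weighted, 2L, ideal)^2)),
       d_minus = sqrt(rowSums(sweep(weighted, 2L, anti_ideal)^2)))
}

#' Closeness coefficient
#'
#' `C = d_minus / (d_plus + d_minus)`, in `[0, 1]`; 1 means the alternative
#' coincides with the ideal solution. When both distances are zero (all
#' alternatives identical) the coefficient is defined as 0.5 with a warning.
#'
#' @param d_plus,d_minus non-negative n-vectors of distances.
#' @return n-vector of closeness coefficients.
#' @export
closeness <- function(d_plus, d_minus) {
  tot <- d_plus + d_minus
  degenerate <- tot == 0
  if (any(degenerate)) {
    warning("zero distance to both ideal and anti-ideal; closeness set to 0.5")
    tot[degenerate] <- 1
    d_minus[degenerate] <- 0.5
  }
  d_minus / tot
}

#' Rank scores descending (1 = best)
#'
#' Exact ties share the smaller rank index by first-occurrence (input)
#' order, so the result is always a permutation of `1..n`.
#'
#' @param scores numeric vector; larger is better.
#' @return integer rank vector.
#' @export
rank_desc <- function(scores) {
  r <- integer(length(scores))
  r[order(-scores)] <- seq_along(scores)  # stable: ties keep input order
  r
}

#' Weighted TOPSIS ranking
#'
#' Ranks the alternatives of a panel by relative closeness to the ideal
#' solution: build the weighted vector-normalized matrix
#' ([weighted_normalized()]), take the componentwise best profile `A+` and
#' worst profile `A-`, compute each row's Euclidean distances `D+`/`D-` to
#' them, and score `C = D-/(D+ + D-)` (rank 1 = largest `C`).
#'
#' @inheritParams weighted_normalized
#' @param weights indicator weights; defaults to [entropy_weights()] of the
#'   panel.
#' @return an object of class `topsis_result`: list with `weighted_matrix`,
#'   `ideal`, `anti_ideal`, `d_plus`, `d_minus`, `closeness`, `ranks`
#'   (named by alternative), and `weights`.
#' @examples
#' res <- topsis(china_mch())
#' round(res$closeness[c("2004", "2018")], 4)
#' @export
topsis <- function(panel, weights = NULL, cotrend = "reciprocal") {
  if (is.null(weights)) weights <- entropy_weights(panel)$weights
  wm <- weighted_normalized(panel, weights, cotrend)
  ideal <- apply(wm, 2L, max)
  anti <- apply(wm, 2L, min)
  d <- topsis_distances(wm, ideal, anti)
  C <- closeness(d$d_plus, d$d_minus)
  structure(list(weighted_matrix = wm, ideal = ideal, anti_ideal = anti,
                 d_plus = stats::setNames(d$d_plus, rownames(wm)),
                 d_minus = stats::setNames(d$d_minus, rownames(wm)),
                 closeness = stats::setNames(C, rownames(wm)),
                 ranks = stats::setNames(rank_desc(C), rownames(wm)),
                 weights = weights),
            class = "topsis_result")
}

#' @export
print.topsis_result <- function(x, digits = 4, ...) {
  cat("weighted TOPSIS\n")
  print(data.frame(d_plus = round(x$d_plus, digits),
                   d_minus = round(x$d_minus, digits),
                   closeness = round(x$closeness, digits),
                   rank = x$ranks))
  invisible(x)
}

#' Write a TOPSIS result table (CSV)
#'
#' One row per alternative: `D+`, `D-`, closeness, rank.
#'
#' @param res a [topsis()] result.
#' @param path output CSV path.
#' @param digits rounding for display values; `NA` writes full precision.
#' @return `path`, invisibly.
#' @export
write_topsis_table <- function(res, path, digits = 4) {
  df <- data.frame(alternative = names(x <- res$closeness),
                   d_plus = res$d_plus, d_minus = res$d_minus,
                   closeness = res$closeness, rank = res$ranks,
                   row.names = NULL)
  if (!is.na(digits))
    df[2:4] <- lapply(df[2:4], round, digits = digits)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
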