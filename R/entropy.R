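#' Column proportions of a normalized matrix
#'
#' `p[i, j] = a[i, j] / sum(a[, j])`: the share of alternative `i` in the
#' column total of indicator `j`. Each non-degenerate column sums to 1.
#'
#' @param normalized non-negative numeric matrix (min-max normalized values).
#' @return matrix of the same shape with unit column sums.
#' @export
column_proportions <- function(normalized) {
  cs <- colSums(normalized)
  if (any(cs <= 0)) {
    cond <- structure(
      class = c("mcdaeval_degenerate_column", "error", "condition"),
      list(message = "zero-sum column: proportions undefined",
           call = sys.call(-1L)))
    stop(cond)
  }
  sweep(normalized, 2L, cs, "/")
}

#' Shannon entropy of one proportion column
#'
#' `e = -(1/log(n)) * sum(p * log(p))` with the convention `0 * log(0) = 0`.
#' The normalizing constant `1/log(n)` scales the maximum (uniform) entropy
#' to 1, so `e` lies in `[0, 1]`.
#'
#' @param p numeric vector of proportions (non-negative, summing to 1).
#' @param n number of alternatives used for the normalizing constant;
#'   defaults to `length(p)`.
#' @return entropy value in `[0, 1]`.
#' @export
column_entropy <- function(p, n = length(p)) {
  if (any(p < 0))
    stop("proportions must be non-negative", call. = FALSE)
  pos <- p[p > 0]
  -sum(pos * log(pos)) / log(n)
}

#' Weights from entropy redundancies
#'
#' Redundancy `d = 1 - e` measures the discriminating information an
#' indicator carries; weights are redundancies normalized to unit sum.
#'
#' @param redundancies non-negative numeric vector, at least one positive.
#' @return weight vector summing to 1.
#' @export
weights_from_redundancy <- function(redundancies) {
  if (any(redundancies < 0))
    stop("redundancies must be non-negative", call. = FALSE)
  tot <- sum(redundancies)
  if (tot == 0)
    stop("all redundancies are zero: the panel carries no information",
         call. = FALSE)
  redundancies / tot
}

#' Entropy weight method
#'
#' Computes objective indicator weights from the dispersion of each
#' indicator across alternatives: min-max normalize each raw column with its
#' direction flag, form column proportions, take normalized Shannon
#' entropies `e_j`, redundancies `d_j = 1 - e_j`, and weights
#' `W_j = d_j / sum(d)`. A more dispersed (informative) indicator receives a
#' larger weight.
#'
#' Constant columns are degenerate (the min-max denominator vanishes); by
#' convention they get `e = 1`, `d = 0`, `W = 0`, and the remaining weights
#' renormalize. A panel in which every column is constant is an error.
#'
#' @param panel an [indicator_panel()].
#' @return an object of class `entropy_weights`: list with `normalized`,
#'   `proportions` (both n x m), `entropies`, `redundancies`, `weights`
#'   (each an m-vector named by indicator).
#' @examples
#' ew <- entropy_weights(china_mch())
#' round(ew$weights, 4)
#' @export
entropy_weights <- function(panel) {
  stopifnot(inherits(panel, "indicator_panel"))
  X <- panel$values
  n <- nrow(X); m <- ncol(X)
  normalized <- matrix(NA_real_, n, m, dimnames = dimnames(X))
  entropies <- stats::setNames(numeric(m), colnames(X))
  degenerate <- logical(m)
  for (j in seq_len(m)) {
    a <- tryCatch(minmax_normalize(X[, j], panel$directions[[j]]),
                  mcdaeval_degenerate_column = function(e) NULL)
    if (is.null(a)) {
      degenerate[j] <- TRUE
      normalized[, j] <- 0
      entropies[j] <- 1
    } else {
      normalized[, j] <- a
    }
  }
  if (all(degenerate))
    stop("every column is constant: entropy weights undefined", call. = FALSE)
  props <- normalized
  props[, !degenerate] <- column_proportions(normalized[, !degenerate, drop = FALSE])
  props[, degenerate] <- NA_real_
  for (j in which(!degenerate))
    entropies[j] <- column_entropy(props[, j], n)
  redundancies <- 1 - entropies
  weights <- weights_from_redundancy(redundancies)
  structure(list(normalized = normalized, proportions = props,
                 entropies = entropies, redundancies = redundancies,
                 weights = weights),
            class = "entropy_weights")
}

#' @export
print.entropy_weights <- function(x, digits = 4, ...) {
  cat("entropy weight method\n")
  print(round(rbind(entropy = x$entropies, redundancy = x$redundancies,
                    weight = x$weights), digits))
  invisible(x)
}

#' Write an entropy weight table (CSV)
#'
#' One row per indicator: entropy, redundancy, weight.
#'
#' @param ew an [entropy_weights()] result.
#' @param path output CSV path.
#' @param digits rounding for display values; `NA` writes full precision.
#' @return `path`, invisibly.
#' @export
write_weights_table <- function(ew, path, digits = 4) {
  df <- data.frame(indicator = names(ew$weights),
                   entropy = ew$entropies,
                   redundancy = ew$redundancies,
                   weight = ew$weights, row.names = NULL)
  if (!is.na(digits))
    df[-1L] <- lapply(df[-1L], round, digits = digits)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
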