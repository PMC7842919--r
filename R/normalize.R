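#' Co-trend configuration
#'
#' Co-trending converts a cost (smaller-is-better) indicator into a
#' larger-is-better one. Two conventions are supported: `difference`
#' (`reference - x`, requiring a reference exceeding every column value) and
#' `reciprocal` (`1/x`, requiring strictly positive values).
#'
#' @param method `"difference"` or `"reciprocal"`.
#' @param reference numeric reference value; required when
#'   `method = "difference"`.
#' @return an object of class `cotrend_config`.
#' @export
cotrend_config <- function(method = c("reciprocal", "difference"),
                           reference = NULL) {
  method <- match.arg(method)
  if (method == "difference") {
    if (is.null(reference) || !is.finite(reference))
      stop("difference co-trend requires a finite reference value",
           call. = FALSE)
  }
  structure(list(method = method, reference = reference),
            class = "cotrend_config")
}

#' Co-trend a cost indicator column
#'
#' @param values numeric vector (one indicator column).
#' @param cfg a [cotrend_config()].
#' @return the co-trended column, same length and order; strictly order
#'   reversing, so the output is larger-is-better.
#' @examples
#' cotrend_column(c(48.3, 18.3), cotrend_config("difference", 100000))
#' cotrend_column(c(48.3, 18.3), cotrend_config("reciprocal"))
#' @export
cotrend_column <- function(values, cfg) {
  stopifnot(inherits(cfg, "cotrend_config"))
  if (cfg$method == "reciprocal") {
    if (any(values <= 0))
      stop("reciprocal co-trend requires strictly positive values",
           call. = FALSE)
    1 / values
  } else {
    if (cfg$reference <= max(values))
      stop(sprintf("difference co-trend reference (%g) must exceed max(x) (%g)",
                   cfg$reference, max(values)), call. = FALSE)
    cfg$reference - values
  }
}

#' Min-max normalization with direction
#'
#' Maps a column to `[0, 1]`: benefit indicators by `(x - min)/(max - min)`,
#' cost indicators by `(max - x)/(max - min)`, so the best value always maps
#' to 1 and the worst to 0. This is the normalization feeding the entropy
#' weight stage.
#'
#' @param values numeric vector.
#' @param direction `"benefit"` or `"cost"`.
#' @return normalized vector in `[0, 1]` containing at least one 0 and one 1.
#'   A constant column is degenerate (the denominator vanishes) and signals
#'   a condition of class `mcdaeval_degenerate_column`; callers that can cope
#'   (see [entropy_weights()]) catch it.
#' @export
minmax_normalize <- function(values, direction = c("benefit", "cost")) {
  direction <- match.arg(direction)
  rng <- range(values)
  if (rng[1L] == rng[2L]) {
    cond <- structure(
      class = c("mcdaeval_degenerate_column", "error", "condition"),
      list(message = "constant column: min-max normalization undefined",
           call = sys.call(-1L)))
    stop(cond)
  }
  if (direction == "benefit") (values - rng[1L]) / (rng[2L] - rng[1L])
  else (rng[2L] - values) / (rng[2L] - rng[1L])
}

#' Euclidean (vector) normalization
#'
#' Divides a column by its Euclidean norm, `x / sqrt(sum(x^2))`, removing the
#' measurement unit. This is the normalization feeding the TOPSIS stage.
#'
#' @param values numeric vector, not all zero.
#' @return vector with unit Euclidean norm.
#' @export
vector_normalize <- function(values) {
  nrm <- sqrt(sum(values^2))
  if (nrm == 0)
    stop("all-zero column: vector normalization undefined", call. = FALSE)
  values / nrm
}
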