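#' Default unitary variation rate grid
#'
#' The 14-scheme grid of unitary variation rates used by the weight
#' sensitivity sweep.
#' @return numeric vector of 14 beta values.
#' @export
default_beta_grid <- function() {
  c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5)
}

#' Raw change rate from a unitary variation rate
#'
#' The unitary variation rate `beta` is the factor by which the perturbed
#' weight's *final, renormalized* value changes (`W'_k = beta * W_k`).
#' `gamma` is the raw pre-normalization multiplier that achieves it:
#' `gamma = (beta - beta * W) / (1 - beta * W)`, valid while
#' `beta * W < 1` (the perturbed weight must stay below 1).
#'
#' @param beta unitary variation rate, `> 0`.
#' @param weight original weight of the perturbed indicator, in `(0, 1)`.
#' @return the raw multiplier `gamma`.
#' @export
gamma_from_beta <- function(beta, weight) {
  if (weight <= 0 || weight >= 1)
    stop("weight must lie strictly between 0 and 1", call. = FALSE)
  if (beta <= 0)
    stop("beta must be positive", call. = FALSE)
  if (beta * weight >= 1)
    stop(sprintf("beta * weight = %g >= 1: perturbed weight would reach 1",
                 beta * weight), call. = FALSE)
  (beta - beta * weight) / (1 - beta * weight)
}

#' Perturb one weight and renormalize
#'
#' Multiplies weight `k` by `gamma_from_beta(beta, weights[k])` and divides
#' the whole vector by its new total. Algebraically the renormalized
#' perturbed weight equals `beta * weights[k]` exactly, and the other
#' weights keep their original pairwise ratios.
#'
#' @param weights m-vector of weights summing to 1.
#' @param k index of the perturbed indicator.
#' @param beta unitary variation rate.
#' @return perturbed m-vector summing to 1.
#' @export
perturb_weights <- function(weights, k, beta) {
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1", call. = FALSE)
  g <- gamma_from_beta(beta, weights[[k]])
  w <- weights
  w[k] <- g * weights[[k]]
  w / sum(w)
}

#' Weight-perturbation sensitivity sweep
#'
#' For each unitary variation rate in `betas`, perturbs the weight of
#' indicator `k` ([perturb_weights()]) and recomputes the full TOPSIS
#' closeness coefficients and ranks under the perturbed weight vector.
#' `beta = 1` leaves the weights, and hence the baseline ranking,
#' unchanged.
#'
#' @inheritParams topsis
#' @param k index (or label) of the perturbed indicator.
#' @param betas grid of unitary variation rates; every `beta * W_k` must be
#'   `< 1`. Defaults to [default_beta_grid()].
#' @return an object of class `sensitivity_sweep`: list with
#'   `perturbed_index`, `betas`, `gammas`, `weight_vectors` (|betas| x m),
#'   `closeness_matrix` and `rank_matrix` (both |betas| x n).
#' @examples
#' sw <- sensitivity_sweep(china_mch(), k = 1, betas = c(0.5, 1, 2))
#' round(sw$weight_vectors, 4)
#' @export
sensitivity_sweep <- function(panel, weights = NULL, k,
                              betas = default_beta_grid(),
                              cotrend = "reciprocal") {
  stopifnot(inherits(panel, "indicator_panel"))
  if (is.null(weights)) weights <- entropy_weights(panel)$weights
  if (is.character(k)) k <- match(k, indicators(panel))
  if (is.na(k) || k < 1L || k > length(weights))
    stop("k does not identify an indicator", call. = FALSE)
  bad <- betas[betas * weights[[k]] >= 1 | betas <= 0]
  if (length(bad))
    stop("invalid beta for W_", k, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  nb <- length(betas)
  wv <- matrix(NA_real_, nb, length(weights),
               dimnames = list(format(betas), names(weights)))
  cm <- matrix(NA_real_, nb, nrow(panel$values),
               dimnames = list(format(betas), alternatives(panel)))
  rm_ <- cm
  gammas <- vapply(betas, gamma_from_beta, numeric(1L),
                   weight = weights[[k]])
  for (b in seq_len(nb)) {
    w <- perturb_weights(weights, k, betas[[b]])
    wv[b, ] <- w
    res <- topsis(panel, weights = w, cotrend = cotrend)
    cm[b, ] <- res$closeness
    rm_[b, ] <- res$ranks
  }
  structure(list(perturbed_index = k, betas = betas, gammas = gammas,
                 weight_vectors = wv, closeness_matrix = cm,
                 rank_matrix = rm_),
            class = "sensitivity_sweep")
}

#' @export
print.sensitivity_sweep <- function(x, digits = 4, ...) {
  cat(sprintf("sensitivity sweep of indicator %d over %d beta values\n",
              x$perturbed_index, length(x$betas)))
  print(round(x$weight_vectors, digits))
  invisible(x)
}

#' Rank crossings along a sensitivity sweep
#'
#' Reports every pair of alternatives whose relative order differs between
#' consecutive beta grid points, with the bracketing beta interval. An
#' empty result means the ranking is stable over the whole grid.
#'
#' @param sweep a [sensitivity_sweep()] result with at least 2 beta values.
#' @return data frame with columns `alt_a`, `alt_b`, `beta_lower`,
#'   `beta_upper`.
#' @export
rank_crossings <- function(sweep) {
  stopifnot(inherits(sweep, "sensitivity_sweep"))
  if (length(sweep$betas) < 2L)
    stop("at least 2 beta values are needed", call. = FALSE)
  R <- sweep$rank_matrix
  alts <- colnames(R)
  out <- list()
  for (b in seq_len(nrow(R) - 1L)) {
    for (i in seq_along(alts)[-length(alts)]) {
      for (j in seq((i + 1L), length(alts))) {
        before <- sign(R[b, i] - R[b, j])
        after <- sign(R[b + 1L, i] - R[b + 1L, j])
        if (before != after)
          out[[length(out) + 1L]] <- data.frame(
            alt_a = alts[i], alt_b = alts[j],
            beta_lower = sweep$betas[b], beta_upper = sweep$betas[b + 1L])
      }
    }
  }
  if (!length(out))
    return(data.frame(alt_a = character(), alt_b = character(),
                      beta_lower = numeric(), beta_upper = numeric()))
  do.call(rbind, out)
}

#' Write sensitivity sweep tables (CSV)
#'
#' `write_sweep_weights` emits one row per beta with the perturbed weight
#' vector; `write_sweep_long` emits a long-format table (`k`, `beta`,
#' `alternative`, `closeness`, `rank`) suitable for plotting closeness
#' curves.
#'
#' @param sweep a [sensitivity_sweep()] result.
#' @param path output CSV path.
#' @param digits rounding for display values; `NA` writes full precision.
#' @return `path`, invisibly.
#' @export
write_sweep_weights <- function(sweep, path, digits = 4) {
  wv <- if (is.na(digits)) sweep$weight_vectors
        else round(sweep$weight_vectors, digits)
  df <- data.frame(beta = sweep$betas, wv, row.names = NULL,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep_weights
#' @export
write_sweep_long <- function(sweep, path, digits = 4) {
  cm <- sweep$closeness_matrix
  df <- data.frame(
    k = sweep$perturbed_index,
    beta = rep(sweep$betas, times = ncol(cm)),
    alternative = rep(colnames(cm), each = nrow(cm)),
    closeness = as.vector(if (is.na(digits)) cm else round(cm, digits)),
    rank = as.vector(sweep$rank_matrix))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
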