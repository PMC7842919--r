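#' Specification for a synthetic indicator panel
#'
#' Describes a panel generator that emulates the structure of a yearly
#' health-indicator table: ordered alternatives with roughly monotone
#' per-indicator trends plus noise, a mixture of benefit and cost
#' indicators, and occasional exact ties between consecutive alternatives.
#'
#' The defaults mirror the bundled real panel: 15 alternatives; one cost
#' indicator starting near 48 and improving (decreasing) by about 2 per
#' step, and five benefit indicators in the 76--90 percent range rising by
#' 0.5--1 per step; Gaussian noise with a scale well below the per-step
#' trend; no forced ties.
#'
#' @param n_alternatives number of alternatives (rows), `>= 2`.
#' @param indicators data frame with one row per indicator and columns
#'   `label`, `direction` (`"benefit"`/`"cost"`), `start` (level at the
#'   first alternative), `trend` (per-step change; negative for improving
#'   cost indicators), `noise` (Gaussian noise scale, `>= 0`), `tie_prob`
#'   (probability a value is copied from the previous alternative, in
#'   `[0, 1)`).
#' @param seed integer seed; generation is deterministic given the spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_alternatives = 15,
                           indicators = default_synthetic_indicators(),
                           seed = 1L) {
  stopifnot(n_alternatives >= 2)
  need <- c("label", "direction", "start", "trend", "noise", "tie_prob")
  if (!all(need %in% names(indicators)))
    stop("indicators must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(indicators$noise < 0))
    stop("noise scale must be >= 0", call. = FALSE)
  if (any(indicators$tie_prob < 0 | indicators$tie_prob >= 1))
    stop("tie_prob must lie in [0, 1)", call. = FALSE)
  if (!all(indicators$direction %in% c("benefit", "cost")))
    stop("unknown direction flag in indicators", call. = FALSE)
  structure(list(n_alternatives = as.integer(n_alternatives),
                 indicators = indicators, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_synthetic_indicators <- function() {
  data.frame(
    label = paste0("X", 1:6),
    direction = c("cost", rep("benefit", 5)),
    start = c(48, 88, 76, 90, 86, 83),
    trend = c(-2.0, 0.5, 1.0, 0.5, 0.6, 1.2),
    noise = c(0.5, 0.3, 0.4, 0.3, 0.3, 0.4),
    tie_prob = rep(0.05, 6))
}

#' Generate a synthetic indicator panel
#'
#' `value[i, j] = start_j + (i - 1) * trend_j + noise`, with independent
#' zero-mean Gaussian noise of scale `noise_j`; with probability
#' `tie_prob_j` a value is copied from the previous alternative, creating
#' an exact within-column tie. Cost columns must come out strictly positive
#' (so the reciprocal co-trend is applicable); noise draws violating
#' positivity are redrawn, and a spec whose deterministic trend itself goes
#' non-positive is an error.
#'
#' @param spec a [synthetic_spec()].
#' @return an [indicator_panel()] with alternatives labelled `A01`, `A02`,
#'   ... in generation order.
#' @examples
#' p <- generate_panel(synthetic_spec(seed = 7))
#' dim(p)
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_alternatives
  ind <- spec$indicators
  set.seed(spec$seed)
  vals <- matrix(NA_real_, n, nrow(ind),
                 dimnames = list(sprintf("A%02d", seq_len(n)), ind$label))
  for (j in seq_len(nrow(ind))) {
    mean_path <- ind$start[j] + (seq_len(n) - 1L) * ind$trend[j]
    if (ind$direction[j] == "cost" && any(mean_path <= 0))
      stop("spec produces non-positive cost trend for ", ind$label[j],
           call. = FALSE)
    x <- mean_path + stats::rnorm(n, 0, ind$noise[j])
    if (ind$direction[j] == "cost") {
      # truncate noise to keep the column reciprocal-safe
      for (tries in seq_len(100L)) {
        neg <- x <= 0
        if (!any(neg)) break
        x[neg] <- mean_path[neg] + stats::rnorm(sum(neg), 0, ind$noise[j])
      }
      if (any(x <= 0))
        stop("could not generate positive cost values for ", ind$label[j],
             call. = FALSE)
    }
    if (ind$tie_prob[j] > 0 && n > 1L) {
      tie <- stats::runif(n - 1L) < ind$tie_prob[j]
      for (i in which(tie)) x[i + 1L] <- x[i]
    }
    vals[, j] <- x
  }
  indicator_panel(vals, stats::setNames(ind$direction, ind$label))
}
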