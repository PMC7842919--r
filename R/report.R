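#' Run configuration for the evaluation pipeline
#'
#' @param panel path to a panel CSV, or an [indicator_panel()] directly.
#' @param schema path to a JSON schema file, or a schema list; ignored when
#'   `panel` is already an `indicator_panel`.
#' @param out output directory for report tables (created if absent).
#' @param ratio_schemes list of fuzzy `(W1, W2)` pairs.
#' @param betas sensitivity beta grid.
#' @param cotrend TOPSIS co-trend method for cost indicators.
#' @param digits rounding digits for display tables (full-precision
#'   companions are always written).
#' @return an object of class `run_config`.
#' @export
run_config <- function(panel, schema = NULL, out = tempfile("mcdaeval_"),
                       ratio_schemes = list(c(0.1, 0.9), c(0.5, 0.5),
                                            c(0.9, 0.1)),
                       betas = default_beta_grid(),
                       cotrend = "reciprocal", digits = 4) {
  if (is.character(panel)) {
    if (!file.exists(panel))
      stop("panel file does not exist: ", panel, call. = FALSE)
    if (is.null(schema))
      stop("a schema is required when panel is a file path", call. = FALSE)
  }
  for (s in ratio_schemes)
    if (length(s) != 2L || abs(sum(s) - 1) > 1e-8)
      stop("every ratio scheme must be a pair summing to 1", call. = FALSE)
  if (digits < 0) stop("digits must be >= 0", call. = FALSE)
  structure(list(panel = panel, schema = schema, out = out,
                 ratio_schemes = ratio_schemes, betas = betas,
                 cotrend = cotrend, digits = digits),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Expected keys: `panel` (CSV path), `schema` (JSON path), optional
#' `out`, `ratio_schemes` (array of pairs), `betas`, `cotrend`, `digits`.
#' Relative paths are resolved against the config file's directory.
#'
#' @param path path to the JSON config.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p)
    if (!is.null(p) && !startsWith(p, "/")) file.path(base, p) else p
  args <- list(panel = resolve(cfg$panel), schema = resolve(cfg$schema))
  if (!is.null(cfg$out)) args$out <- resolve(cfg$out)
  if (!is.null(cfg$ratio_schemes))
    args$ratio_schemes <- lapply(seq_len(nrow(cfg$ratio_schemes)),
                                 function(i) cfg$ratio_schemes[i, ])
  if (!is.null(cfg$betas)) args$betas <- cfg$betas
  if (!is.null(cfg$cotrend)) args$cotrend <- cfg$cotrend
  if (!is.null(cfg$digits)) args$digits <- cfg$digits
  do.call(run_config, args)
}

resolve_panel <- function(config) {
  if (inherits(config$panel, "indicator_panel")) config$panel
  else read_panel(config$panel, config$schema)
}

#' Run the full evaluation pipeline and emit report tables
#'
#' Orchestrates the stages on one panel: entropy weights, weighted TOPSIS,
#' WRSR, fuzzy comprehensive evaluation, and the pairwise Spearman
#' concordance of the three rankings. Writes one CSV per stage (rounded to
#' `config$digits`, with a `*_full.csv` full-precision companion) plus a
#' machine-readable `summary.json`. Any stage error aborts with a
#' stage-named message and removes partial outputs.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage log messages.
#' @return (invisibly) a list with the stage results and the written file
#'   paths.
#' @examples
#' cfg <- run_config(china_mch(), out = tempfile("report_"))
#' res <- run_evaluate(cfg, quiet = TRUE)
#' round(res$fuzzy$comprehensive_rank["2016"], 4)
#' @export
run_evaluate <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  log <- function(...) if (!quiet) message(sprintf(...))
  fail <- function(stage, err) {
    unlink(written)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(err)),
         call. = FALSE)
  }
  stage <- function(name, expr)
    tryCatch(expr, error = function(e) fail(name, e))
  emit <- function(writer, obj, file, ...) {
    p1 <- file.path(config$out, paste0(file, ".csv"))
    p2 <- file.path(config$out, paste0(file, "_full.csv"))
    writer(obj, p1, ..., digits = config$digits)
    writer(obj, p2, ..., digits = NA)
    written <<- c(written, p1, p2)
  }

  panel <- stage("panel_io", resolve_panel(config))
  log("panel: %d alternatives x %d indicators (checksum %.6f)",
      nrow(panel$values), ncol(panel$values), sum(panel$values))

  ew <- stage("entropy_weights", entropy_weights(panel))
  emit(write_weights_table, ew, "weights")
  log("entropy weights: %s",
      paste(round(ew$weights, config$digits), collapse = " "))

  ts <- stage("topsis", topsis(panel, ew$weights, config$cotrend))
  emit(write_topsis_table, ts, "topsis")
  log("topsis: best = %s", names(which.min(ts$ranks)))

  rs <- stage("rsr", wrsr(panel, ew$weights))
  emit(function(obj, path, digits) write_wrsr_table(panel, obj, path,
                                                    digits = digits),
       rs, "wrsr")
  log("wrsr: best = %s", names(which.min(rs$ranks)))

  fz <- stage("fuzzy_combine",
              fuzzy_evaluate(ts$closeness, rs$wrsr, config$ratio_schemes))
  emit(write_fuzzy_table, fz, "fuzzy")

  cc <- stage("concordance", {
    balanced <- which.min(vapply(config$ratio_schemes,
                                 function(s) abs(s[1L] - 0.5), numeric(1L)))
    concordance_table(ts$ranks, rs$ranks, fz$scheme_ranks[, balanced])
  })
  ccp <- file.path(config$out, "concordance.csv")
  utils::write.csv(
    transform(cc, rho = round(rho, config$digits)),
    ccp, row.names = FALSE, quote = FALSE)
  written <- c(written, ccp)
  log("concordance: rho = %s", paste(round(cc$rho, 3), collapse = " "))

  summary_path <- file.path(config$out, "summary.json")
  jsonlite::write_json(list(
    n_alternatives = nrow(panel$values),
    n_indicators = ncol(panel$values),
    weights = as.list(ew$weights),
    topsis_ranks = as.list(ts$ranks),
    wrsr_ranks = as.list(rs$ranks),
    comprehensive_ranks = as.list(fz$comprehensive_rank),
    concordance = cc), summary_path, auto_unbox = TRUE, digits = NA)
  written <- c(written, summary_path)

  invisible(list(panel = panel, weights = ew, topsis = ts, wrsr = rs,
                 fuzzy = fz, concordance = cc, files = written))
}

#' Run the weight sensitivity sweep and emit report tables
#'
#' For indicator `k` (or every indicator when `k = "all"`), sweeps the beta
#' grid of `config`, writing a per-beta weight table
#' (`sensitivity_weights_k<k>.csv`) and a long-format closeness table
#' (`sensitivity_long_k<k>.csv`) per indicator.
#'
#' @param config a [run_config()].
#' @param k indicator index, label, or `"all"`.
#' @param quiet suppress log messages.
#' @return (invisibly) a list of [sensitivity_sweep()] results, one per
#'   swept indicator.
#' @export
run_sensitivity <- function(config, k = "all", quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  panel <- resolve_panel(config)
  ew <- entropy_weights(panel)
  ks <- if (identical(k, "all")) seq_len(ncol(panel$values))
        else if (is.character(k)) match(k, indicators(panel))
        else as.integer(k)
  sweeps <- lapply(ks, function(kk) {
    sw <- sensitivity_sweep(panel, ew$weights, kk, config$betas,
                            config$cotrend)
    write_sweep_weights(sw, file.path(
      config$out, sprintf("sensitivity_weights_k%d.csv", kk)),
      digits = config$digits)
    write_sweep_long(sw, file.path(
      config$out, sprintf("sensitivity_long_k%d.csv", kk)),
      digits = config$digits)
    if (!quiet)
      message(sprintf("sensitivity k=%d: %d crossings over %d betas", kk,
                      nrow(rank_crossings(sw)), length(config$betas)))
    sw
  })
  names(sweeps) <- indicators(panel)[ks]
  invisible(sweeps)
}
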