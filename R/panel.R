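#' Construct an indicator panel
#'
#' An `indicator_panel` is the central data container of the package: a
#' rectangular matrix of `n >= 2` alternatives (rows, e.g. years) by
#' `m >= 1` indicators (columns), together with a per-indicator direction
#' flag and, optionally, a per-indicator reference value used by the
#' difference co-trend of cost indicators.
#'
#' @param values numeric matrix with unique row names (alternative labels)
#'   and unique column names (indicator labels); no missing values allowed.
#' @param directions character vector of `"benefit"` (larger is better) or
#'   `"cost"` (smaller is better), one per indicator. May be named by
#'   indicator label; unnamed vectors are matched by position.
#' @param cost_reference optional numeric vector of reference values for
#'   difference co-trending, named by indicator label (only meaningful for
#'   cost indicators). Each reference must exceed every value in its column.
#'
#' @return an object of class `indicator_panel`: a list with elements
#'   `values`, `directions` (named), and `cost_reference` (named, `NA` where
#'   absent).
#' @examples
#' p <- indicator_panel(
#'   matrix(c(10, 8, 6, 70, 80, 90), nrow = 3,
#'          dimnames = list(2001:2003, c("mortality", "coverage"))),
#'   directions = c(mortality = "cost", coverage = "benefit"))
#' p
#' @seealso [read_panel()], [china_mch()], [generate_panel()]
#' @export
indicator_panel <- function(values, directions, cost_reference = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("panel values must be numeric", call. = FALSE)
  if (nrow(values) < 2L)
    stop("panel needs at least 2 alternatives (rows)", call. = FALSE)
  if (ncol(values) < 1L)
    stop("panel needs at least 1 indicator (column)", call. = FALSE)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row %d, column %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (is.null(rownames(values)))
    rownames(values) <- as.character(seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("X", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate alternative labels: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate indicator labels: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)

  m <- ncol(values)
  if (length(directions) != m)
    stop(sprintf("directions has %d entries but the panel has %d indicators",
                 length(directions), m), call. = FALSE)
  if (!is.null(names(directions))) {
    if (!setequal(names(directions), colnames(values)))
      stop("names of directions do not match the indicator labels",
           call. = FALSE)
    directions <- directions[colnames(values)]
  } else {
    names(directions) <- colnames(values)
  }
  ok <- directions %in% c("benefit", "cost")
  if (!all(ok))
    stop("unknown direction flag for indicator ",
         paste(names(directions)[!ok], collapse = ", "),
         " (must be 'benefit' or 'cost')", call. = FALSE)

  ref <- rep(NA_real_, m)
  names(ref) <- colnames(values)
  if (!is.null(cost_reference) && length(cost_reference)) {
    if (is.null(names(cost_reference)))
      stop("cost_reference must be named by indicator label", call. = FALSE)
    unknown <- setdiff(names(cost_reference), colnames(values))
    if (length(unknown))
      stop("cost_reference names not in the panel: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (lab in names(cost_reference)) {
      if (cost_reference[[lab]] <= max(values[, lab]))
        stop(sprintf(
          "cost_reference for %s (%g) must exceed every column value (max %g)",
          lab, cost_reference[[lab]], max(values[, lab])), call. = FALSE)
      ref[lab] <- cost_reference[[lab]]
    }
  }

  structure(list(values = values, directions = directions,
                 cost_reference = ref),
            class = "indicator_panel")
}

#' @export
print.indicator_panel <- function(x, ...) {
  cat(sprintf("indicator_panel: %d alternatives x %d indicators\n",
              nrow(x$values), ncol(x$values)))
  cat("directions:",
      paste(sprintf("%s=%s", names(x$directions),
                    ifelse(x$directions == "cost", "cost", "benefit")),
            collapse = " "), "\n")
  print(x$values, ...)
  invisible(x)
}

#' @export
dim.indicator_panel <- function(x) dim(x$values)

#' Alternative and indicator labels of a panel
#' @param panel an [indicator_panel()].
#' @return character vector of labels, in panel order.
#' @export
alternatives <- function(panel) rownames(panel$values)

#' @rdname alternatives
#' @export
indicators <- function(panel) colnames(panel$values)

#' Read an indicator panel from a CSV file
#'
#' The file dialect is fixed: comma-separated, UTF-8, decimal point, one
#' header row of indicator labels, and a first column of alternative labels.
#' Direction metadata is not stored in the data file; it is supplied by a
#' sidecar schema (see [read_schema()]).
#'
#' @param path path to the CSV file.
#' @param schema either a schema list as returned by [read_schema()], or the
#'   path to a JSON schema file.
#' @return a validated [indicator_panel()]; row and column order are
#'   preserved from the file.
#' @examples
#' panel_csv <- system.file("extdata", "china_mch_raw.csv", package = "mcdaeval")
#' schema_json <- system.file("extdata", "china_mch_schema.json", package = "mcdaeval")
#' p <- read_panel(panel_csv, schema_json)
#' dim(p)
#' @export
read_panel <- function(path, schema) {
  if (!file.exists(path))
    stop("panel file does not exist: ", path, call. = FALSE)
  if (is.character(schema))
    schema <- read_schema(schema)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (ncol(raw) < 2L)
    stop("panel file must have a label column plus at least one indicator",
         call. = FALSE)
  labs <- raw[[1L]]
  vals <- raw[-1L]
  num <- suppressWarnings(
    vapply(vals, as.numeric, numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(labs, names(vals)))
  bad <- which(is.na(num) | !nzchar(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric or blank cell at row '%s', column '%s'",
                 labs[bad[1L, 1L]], colnames(num)[bad[1L, 2L]]),
         call. = FALSE)
  dirs <- vapply(colnames(num), function(lab) {
    if (is.null(schema[[lab]]))
      stop("indicator '", lab, "' missing from schema", call. = FALSE)
    schema[[lab]]$direction
  }, character(1L))
  refs <- unlist(lapply(colnames(num), function(lab) {
    r <- schema[[lab]]$cost_reference
    if (is.null(r)) NULL else stats::setNames(as.numeric(r), lab)
  }))
  indicator_panel(num, dirs, refs)
}

#' Write an indicator panel to a CSV file
#'
#' Inverse of [read_panel()]: `read_panel(write_panel(p, f), schema)`
#' round-trips any valid panel whose schema matches.
#'
#' @param panel an [indicator_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "indicator_panel"))
  df <- data.frame(alternative = rownames(panel$values),
                   panel$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read or write a panel schema (direction metadata sidecar)
#'
#' A schema is a JSON object keyed by indicator label, each entry holding
#' `direction` (`"benefit"` or `"cost"`) and optionally `cost_reference`
#' (numeric, for difference co-trending) and `cotrend` (`"reciprocal"` or
#' `"difference"`, the TOPSIS co-trend method for that cost indicator).
#'
#' @param path path to a JSON schema file.
#' @return a named list of per-indicator entries.
#' @export
read_schema <- function(path) {
  if (!file.exists(path))
    stop("schema file does not exist: ", path, call. = FALSE)
  schema <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (lab in names(schema)) {
    d <- schema[[lab]]$direction
    if (is.null(d) || !d %in% c("benefit", "cost"))
      stop("schema entry '", lab, "' has missing or unknown direction flag",
           call. = FALSE)
  }
  schema
}

#' @rdname read_schema
#' @param panel an [indicator_panel()] whose metadata should be serialized.
#' @param cotrend optional named character vector giving the TOPSIS co-trend
#'   method per cost indicator.
#' @export
write_schema <- function(panel, path, cotrend = NULL) {
  stopifnot(inherits(panel, "indicator_panel"))
  schema <- lapply(indicators(panel), function(lab) {
    entry <- list(direction = unname(panel$directions[[lab]]))
    if (!is.na(panel$cost_reference[[lab]]))
      entry$cost_reference <- unname(panel$cost_reference[[lab]])
    if (!is.null(cotrend) && lab %in% names(cotrend))
      entry$cotrend <- unname(cotrend[[lab]])
    entry
  })
  names(schema) <- indicators(panel)
  jsonlite::write_json(schema, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
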