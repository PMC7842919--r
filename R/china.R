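#' Bundled panel: maternal health care indicators, China 2004--2018
#'
#' Fifteen years by six indicators from the China Health Statistics Yearbook
#' 2019: maternal mortality rate `X1` (deaths per 100,000, a cost indicator)
#' and five benefit indicators in percent -- registration rate `X2`, system
#' management rate `X3`, prenatal check-up rate `X4`, postpartum visit rate
#' `X5`, and hospital delivery rate `X6`.
#'
#' `form = "raw"` returns the indicators as published. `form = "cotrended"`
#' returns the same panel with the mortality column difference co-trended
#' against the reference 100,000 (`100000 - X1`), so that every column is
#' larger-is-better; the five benefit columns are identical in both forms.
#'
#' @param form `"raw"` (default) or `"cotrended"`.
#' @return an [indicator_panel()]; 15 rows (years 2004--2018), 6 columns.
#'   The raw form carries `cost_reference = 100000` for `X1`.
#' @examples
#' china_mch()$values["2004", "X1"]        # 48.3
#' china_mch("cotrended")$values["2004", "X1"]  # 99951.7
#' @export
china_mch <- function(form = c("raw", "cotrended")) {
  form <- match.arg(form)
  years <- as.character(2004:2018)
  vals <- matrix(c(
    # X1     X2    X3    X4    X5    X6
    48.3, 88.3, 76.4, 89.7, 85.9, 82.8,
    47.7, 88.5, 76.7, 89.8, 86.0, 85.9,
    41.1, 88.2, 76.5, 89.7, 85.7, 88.4,
    36.6, 89.3, 77.3, 90.9, 86.7, 91.7,
    34.2, 89.3, 78.1, 91.0, 87.0, 94.5,
    31.9, 90.9, 80.9, 92.2, 88.7, 96.3,
    30.0, 92.9, 84.1, 94.1, 90.8, 97.8,
    26.1, 93.8, 85.2, 93.7, 91.0, 98.7,
    24.5, 94.8, 87.6, 95.0, 92.6, 99.2,
    23.2, 95.7, 89.5, 95.6, 93.5, 99.5,
    21.7, 95.8, 90.0, 96.2, 93.9, 99.6,
    20.1, 96.4, 91.5, 96.5, 94.5, 99.7,
    19.9, 96.6, 91.6, 96.6, 94.6, 99.8,
    19.6, 96.6, 89.6, 96.5, 94.0, 99.9,
    18.3, 92.5, 89.9, 96.6, 93.8, 99.9),
    nrow = 15L, byrow = TRUE,
    dimnames = list(years, paste0("X", 1:6)))
  if (form == "cotrended") {
    vals[, "X1"] <- 100000 - vals[, "X1"]
    indicator_panel(vals, c("benefit", "benefit", "benefit",
                            "benefit", "benefit", "benefit"))
  } else {
    indicator_panel(vals,
                    c("cost", "benefit", "benefit",
                      "benefit", "benefit", "benefit"),
                    cost_reference = c(X1 = 100000))
  }
}
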