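#' Load a packaged reference table
#'
#' The package ships the printed result tables of a national 39-hospital
#' efficiency study as plain-CSV fixtures, stored exactly at their printed
#' precision (4 decimals for efficiency scores, 3 for Malmquist indices).
#' They serve as worked-example inputs for the summary, decomposition and
#' model-comparison routines, and as regression anchors for the test suite.
#'
#' Available fixtures:
#' \describe{
#'   \item{`factors_2019`}{environmental covariates per hospital: `Z1` ratio
#'     of outpatient episodes to inpatient days, `Z2` sole-hospital
#'     indicator, `Z3` proportion of over-65s in the catchment area, `Z4`
#'     proportion of infants, `Z5` bed turnover rate, `Z6` bed occupation
#'     rate (%), `Z7` average length of stay (days), and mutually exclusive
#'     size dummies `D1` (very large, >= 600 beds), `D2` (400-599), `D3`
#'     (200-399); all three zero marks a small (< 200 beds) hospital,
#'     carried by the regression constant. The reference year is 2019 (the
#'     table's caption leaves it implicit).}
#'   \item{`scores_2019`}{2019 efficiency scores: `crs`, `vrs`, `se`,
#'     intensity-weight sum `lambda_sum`, returns-to-scale label `rts`, and
#'     the peer list `peers` (semicolon-separated, labels zero-padded).}
#'   \item{`crs_panel`}{CRS scores 2015-2019 per hospital (`crs_<year>`),
#'     the printed returns-to-scale marker per year (`rts_<year>`;
#'     `frontier` for score 1, empty where the source prints none), and the
#'     number of years on the frontier.}
#'   \item{`malmquist`}{whole-period Malmquist decomposition per hospital
#'     (`tfpch`, `tech`, `ech`, `pech`, `sech`) plus the four
#'     adjacent-period averages and the overall 2015-2019 average, keyed by
#'     `unit`.}
#'   \item{`tobit_models`}{the six candidate censored-regression models in
#'     long form (`model`, `term`, `estimate`, significance stars), with
#'     fit metadata rows (`wald_chi2`, `log_likelihood`, `n_obs`,
#'     `n_groups`, `obs_per_group`, `prob_chi2`).}
#' }
#'
#' @param name one of `"factors_2019"`, `"scores_2019"`, `"crs_panel"`,
#'   `"malmquist"`, `"tobit_models"`.
#' @return a data.frame, values exactly as printed in the source tables.
#' @examples
#' sc <- load_fixture("scores_2019")
#' sc[sc$dmu == "H09", c("crs", "vrs", "se")]
#' @export
load_fixture <- function(name) {
  available <- c("factors_2019", "scores_2019", "crs_panel",
                 "malmquist", "tobit_models")
  if (!is.character(name) || length(name) != 1L || !name %in% available) {
    stop("unknown fixture '", paste(name, collapse = ","), "'; available: ",
         paste(available, collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "hospeff",
                      mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  na.strings = character())
}
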