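#' Example stroke-case reference tables
#'
#' Per-location results of two published example assessments (two chronic
#' stroke patients, both hands each), shipped as plain-text reference data:
#'
#' * `example_case_metrics()` -- offset and spread in cm for each of the 24
#'   stimulation sites, normalized to the 17 cm reference hand.
#' * `example_case_nsa()` -- the clinical localization subscale rating
#'   (0/1/2) at each of the six NSA locations.
#'
#' These tables are the printed per-location values only; the underlying raw
#' response coordinates are not available. They are used to exercise the
#' aggregation layer (per-site values to hand-level means) and the NSA total.
#'
#' @return a tibble; one row per case, hand and location.
#' @examples
#' m <- example_case_metrics()
#' dplyr::count(m, case, hand)
#' @export
example_case_metrics <- function() {
  path <- system.file("extdata", "example_cases_metrics.csv",
                      package = "tactloc", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    case = "c", hand = "c", laterality = "c",
                    site_id = "i", offset_cm = "d", spread_cm = "d"
                  ))
}

#' @rdname example_case_metrics
#' @export
example_case_nsa <- function() {
  path <- system.file("extdata", "example_cases_nsa.csv",
                      package = "tactloc", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    case = "c", hand = "c", laterality = "c",
                    location = "c", rating = "i"
                  ))
}
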