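#' Published national CDC workforce series for China, 2019-2023
#'
#' Accessors for the small published national tables bundled with the
#' package: the annual staff totals with density per 10,000 population
#' and health-professional share, the composition breakdown (gender, age
#' bands, tenure bands), and the within-/between-region Theil
#' decomposition rows. These are the printed national aggregates; the
#' underlying provincial microdata are not public, which is why synthetic
#' panels carry the estimator-level validation.
#'
#' @details The published tenure percentages do not close to 100 in every
#' year (2019 sums to 95.63, 2023 to 101.77 as printed), so
#' `china_cdc_breakdown()` loads them with the partition check disabled
#' and leaves the cells exactly as published.
#'
#' @return `china_cdc_density()`: a tibble with `year`, `staff_total`,
#'   `density_per_10k`, `health_professional_percent`.
#'   `china_cdc_breakdown()`: a breakdown tibble as from
#'   [read_breakdown()]. `china_cdc_theil_decomposition()`: a tibble of
#'   published overall/within/between Theil components per (category,
#'   index kind, year).
#' @examples
#' china_cdc_density()
#' proportion_sum(china_cdc_breakdown(), 2023, "tenure", c("20-29", ">=30"))
#' @export
china_cdc_density <- function() {
  path <- system.file("extdata", "china_cdc_density_2019_2023.csv",
                      package = "hwequity", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname china_cdc_density
#' @export
china_cdc_breakdown <- function() {
  path <- system.file("extdata", "china_cdc_breakdown_2019_2023.csv",
                      package = "hwequity", mustWork = TRUE)
  read_breakdown(path, check_sums = FALSE)
}

#' @rdname china_cdc_density
#' @export
china_cdc_theil_decomposition <- function() {
  path <- system.file("extdata",
                      "china_cdc_theil_decomposition_2019_2023.csv",
                      package = "hwequity", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
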