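#' Configuration for the synthetic workforce-panel generator
#'
#' Builds a validated configuration for [generate_panel()]. Defaults
#' emulate a mainland-China-like study panel: 31 provincial units split
#' 11/8/12 across three health regions, five annual waves, workforce
#' densities around 1.4 staff per 10,000 population with log-normal
#' within-region dispersion, and a modest annual density drift.
#'
#' @param n_units_per_region Named integer vector, units per region label.
#' @param years Integer vector of calendar years (strictly increasing).
#' @param mean_log_density Named numeric vector (same names as
#'   `n_units_per_region`): log-scale location of the first-year density
#'   in workers per 10,000 population.
#' @param sigma_within Log-scale standard deviation of density within a
#'   region (>= 0).
#' @param population_range Length-2 numeric, min/max unit population.
#' @param gdp_per_capita_range Length-2 numeric, min/max GDP per capita
#'   (currency units).
#' @param area_range Length-2 numeric, min/max unit land area in km^2.
#' @param professional_fraction Fraction of staff who are health
#'   professionals, in (0, 1].
#' @param annual_density_growth Multiplicative density drift per year
#'   (0.05 = +5%/year).
#' @param seed Integer seed; the same seed always yields the same panel.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_units_per_region = c(eastern = 11, central = 8,
                                                    western = 12),
                             years = 2019:2023,
                             mean_log_density = c(eastern = 0.45,
                                                  central = 0.20,
                                                  western = 0.25),
                             sigma_within = 0.33,
                             population_range = c(3e6, 1.2e8),
                             gdp_per_capita_range = c(3e4, 2e5),
                             area_range = c(1e4, 1.7e6),
                             professional_fraction = 0.74,
                             annual_density_growth = 0.06,
                             seed = 1L) {
  if (length(n_units_per_region) == 0 || is.null(names(n_units_per_region)) ||
      any(names(n_units_per_region) == "")) {
    hw_stop("n_units_per_region must be a non-empty named vector",
            "hw_config_error")
  }
  if (any(n_units_per_region < 1)) {
    hw_stop("each region needs at least one unit", "hw_config_error")
  }
  if (!setequal(names(mean_log_density), names(n_units_per_region))) {
    hw_stop("mean_log_density names must match n_units_per_region",
            "hw_config_error")
  }
  check_range <- function(r, nm) {
    if (length(r) != 2 || r[1] > r[2] || r[1] <= 0) {
      hw_stop(paste0(nm, " must be a positive (min, max) pair"),
              "hw_config_error")
    }
  }
  check_range(population_range, "population_range")
  check_range(gdp_per_capita_range, "gdp_per_capita_range")
  check_range(area_range, "area_range")
  if (sigma_within < 0) hw_stop("sigma_within must be >= 0", "hw_config_error")
  if (professional_fraction <= 0 || professional_fraction > 1) {
    hw_stop("professional_fraction must lie in (0, 1]", "hw_config_error")
  }
  if (length(years) < 1 || any(diff(years) <= 0)) {
    hw_stop("years must be strictly increasing", "hw_config_error")
  }
  structure(list(n_units_per_region = n_units_per_region,
                 years = as.integer(years),
                 mean_log_density = mean_log_density[names(n_units_per_region)],
                 sigma_within = sigma_within,
                 population_range = population_range,
                 gdp_per_capita_range = gdp_per_capita_range,
                 area_range = area_range,
                 professional_fraction = professional_fraction,
                 annual_density_growth = annual_density_growth,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic workforce panel
#'
#' Draws, for each unit, a population, GDP and land area uniformly from
#' the configured ranges (held constant across years), and for each
#' (unit, year) a workforce density
#' \deqn{x_{it} \sim \mathrm{LogNormal}(\mu_{r(i)} + t\,\log(1+g),\ \sigma_w^2)}
#' in workers per 10,000 population, where \eqn{\mu_r} is the region's
#' log-scale location, \eqn{g} the annual growth and \eqn{t} years since
#' the first wave. Staff counts are `round(density * population / 10000)`
#' and health professionals `round(fraction * staff)`, so counts are
#' integers as in real registry data. All draws flow from the single
#' configured seed; the global RNG state is left untouched.
#'
#' @param config A [synthetic_config()].
#' @return A validated [workforce_panel()].
#' @export
generate_panel <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  regions <- names(config$n_units_per_region)
  n_total <- sum(config$n_units_per_region)
  withr::with_seed(config$seed, {
    unit_region <- rep(regions, times = config$n_units_per_region)
    units <- sprintf("%s_unit_%02d", unit_region,
                     unlist(lapply(config$n_units_per_region, seq_len)))
    population <- runif(n_total, config$population_range[1],
                        config$population_range[2])
    gdp_pc <- runif(n_total, config$gdp_per_capita_range[1],
                    config$gdp_per_capita_range[2])
    area <- runif(n_total, config$area_range[1], config$area_range[2])
    rows <- lapply(seq_along(config$years), function(k) {
      drift <- (k - 1) * log1p(config$annual_density_growth)
      dens <- rlnorm(n_total,
                     meanlog = config$mean_log_density[unit_region] + drift,
                     sdlog = config$sigma_within)
      staff <- round(dens * population / 1e4)
      tibble::tibble(unit = units, region = unit_region,
                     year = config$years[k],
                     population = population, gdp = gdp_pc * population,
                     area_km2 = area, staff = staff,
                     health_professionals =
                       round(config$professional_fraction * staff))
    })
  })
  workforce_panel(dplyr::bind_rows(rows))
}

#' Closed-form inequality references for a log-normal density field
#'
#' For an equal-weight field of log-normal densities with log-scale
#' dispersion `sigma`, the population Gini coefficient is
#' \eqn{2\Phi(\sigma/\sqrt{2}) - 1} and both Theil T and Theil L equal
#' \eqn{\sigma^2/2}. Used as the ground truth when validating the sample
#' estimators on synthetic panels.
#'
#' @param sigma Log-scale standard deviation (>= 0).
#' @return A list with components `gini` and `theil`.
#' @examples
#' lognormal_reference(0.5)
#' @export
lognormal_reference <- function(sigma) {
  if (sigma < 0) hw_stop("sigma must be >= 0", "hw_domain_error")
  list(gini = 2 * pnorm(sigma / sqrt(2)) - 1,
       theil = sigma^2 / 2)
}

#' Zero out the workforce of one panel record
#'
#' Returns a copy of the panel with `staff` and `health_professionals`
#' set to 0 for the given (unit, year). Useful for exercising the
#' zero-worker pathology: Theil L becomes undefined (its geometric mean
#' collapses) while Theil T remains finite.
#'
#' @param panel A `workforce_panel`.
#' @param unit Unit name.
#' @param year Calendar year.
#' @return The modified panel.
#' @export
inject_zero_unit <- function(panel, unit, year) {
  stopifnot(inherits(panel, "workforce_panel"))
  hit <- panel$unit == unit & panel$year == year
  if (!any(hit)) {
    hw_stop(paste0("no record for unit '", unit, "' in year ", year),
            "hw_lookup_error")
  }
  panel$staff[hit] <- 0
  panel$health_professionals[hit] <- 0
  panel
}
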