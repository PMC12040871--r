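#' Workforce density per scaling unit of a denominator
#'
#' Density is `workers / denominator * per`; with the default
#' `per = 10000` and a population denominator this is the conventional
#' "staff per 10,000 population". The same formula generalizes to GDP or
#' land-area denominators.
#'
#' @param workers Worker count (>= 0).
#' @param denominator Dimension quantity (population, GDP or km^2; > 0).
#' @param per Scaling constant (default 10,000).
#' @return Numeric density.
#' @examples
#' density_per(200000, 328330000)  # 6.09 per 10,000
#' @export
density_per <- function(workers, denominator, per = 1e4) {
  if (any(denominator <= 0)) {
    hw_stop("denominator must be strictly positive", "hw_domain_error")
  }
  if (any(workers < 0)) hw_stop("workers must be >= 0", "hw_domain_error")
  workers / denominator * per
}

#' Linear trend test for a short annual series
#'
#' Ordinary least squares of the value on calendar year; the trend test
#' is the two-sided t-test of the slope with n - 2 degrees of freedom,
#' the standard "p for trend" on short annual series. Results are
#' invariant to affine recoding of the year axis.
#'
#' @param values Numeric series.
#' @param years Matching, strictly increasing years.
#' @return A tibble with `slope`, `intercept` (level at the first year),
#'   `t_stat`, `df`, `p_value` and a `degenerate` flag set when the fit
#'   has zero residual variance with a nonzero slope (p is then 0).
#' @examples
#' linear_trend_test(c(1.30, 1.38, 1.45, 1.59, 1.64), 2019:2023)
#' @export
linear_trend_test <- function(values, years) {
  n <- length(values)
  if (n != length(years)) hw_stop("values and years differ in length",
                                  "hw_domain_error")
  if (n < 3) hw_stop("need at least 3 points for a trend test",
                     "hw_insufficient_data_error")
  if (any(diff(years) <= 0)) hw_stop("years must be strictly increasing",
                                     "hw_domain_error")
  fit <- lm(values ~ years)
  slope <- unname(coef(fit)["years"])
  df <- n - 2L
  rss <- sum(residuals(fit)^2)
  sxx <- sum((years - mean(years))^2)
  scale2 <- max(1, sum(values^2))
  perfect_fit <- rss < 1e-20 * scale2
  slope_is_zero <- slope^2 * sxx < 1e-20 * scale2
  if (perfect_fit && !slope_is_zero) {   # exact line, nonzero slope
    degenerate <- TRUE
    t_stat <- Inf * sign(slope)
    p <- 0
  } else if (perfect_fit) {              # flat series: no trend at all
    degenerate <- FALSE
    slope <- 0
    t_stat <- 0
    p <- 1
  } else {
    degenerate <- FALSE
    se <- sqrt(rss / df / sxx)
    t_stat <- slope / se
    p <- 2 * pt(-abs(t_stat), df)
  }
  tibble::tibble(slope = slope,
                 intercept = unname(coef(fit)[1] + slope * years[1]),
                 t_stat = t_stat, df = df, p_value = p,
                 degenerate = degenerate)
}

#' Sum selected composition percentages
#'
#' Adds the printed percentages for a label subset of one category group
#' in one year, e.g. the share of staff with 20 or more years of service
#' as the sum of the 20-29 and >=30 tenure cells.
#'
#' @param breakdown A breakdown tibble as returned by [read_breakdown()].
#' @param year Calendar year.
#' @param group Category group (e.g. `"tenure"`, `"age"`).
#' @param labels Character vector of category labels to sum; empty set
#'   returns 0.
#' @return Numeric percentage.
#' @export
proportion_sum <- function(breakdown, year, group, labels) {
  if (length(labels) == 0) return(0)
  sub <- breakdown[breakdown$year == year &
                     breakdown$category_group == group, , drop = FALSE]
  miss <- setdiff(labels, sub$category_label)
  if (length(miss) > 0) {
    hw_stop(paste0("label(s) not found for ", group, " ", year, ": ",
                   paste(miss, collapse = ", ")), "hw_lookup_error")
  }
  sum(sub$percent[sub$category_label %in% labels])
}

scope_rows <- function(panel, scope) {
  if (identical(scope, "national")) return(panel)
  rows <- panel[panel$region == scope, , drop = FALSE]
  if (nrow(rows) == 0) {
    hw_stop(paste0("scope '", scope, "' selects no units"),
            "hw_domain_error")
  }
  rows
}

#' Per-year workforce density series for a scope
#'
#' For each year in the panel, sums the worker counts over the scope
#' (the whole panel or one region) and divides by the summed population,
#' scaled per 10,000. The national series is therefore the
#' population-weighted mean of the regional series.
#'
#' @param panel A `workforce_panel`.
#' @param scope `"national"` or a region label.
#' @param category `"staff"` or `"health_professionals"`.
#' @return A tibble with `year`, `workers`, `population`, `density`.
#' @export
density_series <- function(panel, scope = "national", category = "staff") {
  stopifnot(inherits(panel, "workforce_panel"))
  category <- match.arg(category, c("staff", "health_professionals"))
  rows <- scope_rows(panel, scope)
  out <- dplyr::summarise(dplyr::group_by(rows, .data$year),
                          workers = sum(.data[[category]]),
                          population = sum(.data$population),
                          .groups = "drop")
  out$density <- density_per(out$workers, out$population)
  tibble::as_tibble(out[order(out$year), ])
}

#' Staffing gap against a target density
#'
#' Generic utility: the number of additional workers needed to reach a
#' target density over a given population, `target/per * population -
#' current_workers`, floored at zero.
#'
#' @param current_workers Current worker count.
#' @param population Population covered.
#' @param target_density Target workers per `per` population.
#' @param per Scaling constant (default 10,000).
#' @return Numeric gap (0 when the target is already met).
#' @export
staffing_gap <- function(current_workers, population, target_density,
                         per = 1e4) {
  pmax(0, target_density / per * population - current_workers)
}
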