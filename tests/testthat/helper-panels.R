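# Build a small balanced panel from explicit staff counts.
make_panel <- function(staff,
                       population = rep(1e7, length(staff)),
                       gdp = population * 5e4,
                       area = rep(1e5, length(staff)),
                       regions = rep("r1", length(staff)),
                       years = 2023,
                       professional_fraction = 1) {
  n <- length(staff)
  units <- sprintf("u%02d", seq_len(n))
  rows <- do.call(rbind, lapply(years, function(y) {
    data.frame(unit = units, region = regions, year = y,
               population = population, gdp = gdp, area_km2 = area,
               staff = staff,
               health_professionals = round(professional_fraction * staff))
  }))
  workforce_panel(rows)
}

# Shares table straight from raw counts and weights, bypassing the panel.
shares_from_raw <- function(h, p, units = sprintf("u%02d", seq_along(h))) {
  tibble::tibble(unit = units,
                 resource_share = h / sum(h),
                 dimension_share = p / sum(p),
                 density = h / p)
}

# Independent Theil oracles: explicit loops over share lists built from
# raw counts, no vectorized shortcuts shared with the implementation.
oracle_theil_T <- function(h, p) {
  H <- sum(h); P <- sum(p); s <- 0
  for (i in seq_along(h)) {
    if (h[i] > 0) s <- s + (h[i] / H) * log((h[i] / H) / (p[i] / P))
  }
  s
}

oracle_theil_L <- function(h, p) {
  H <- sum(h); P <- sum(p); s <- 0
  for (i in seq_along(h)) {
    xi <- h[i] / p[i]
    s <- s + (p[i] / P) * log((H / P) / xi)
  }
  s
}

# Brute-force OLS trend oracle via the normal equations.
oracle_trend <- function(values, years) {
  n <- length(values)
  xbar <- mean(years); ybar <- mean(values)
  sxx <- sum((years - xbar)^2)
  slope <- sum((years - xbar) * (values - ybar)) / sxx
  intercept <- ybar - slope * xbar
  resid <- values - intercept - slope * years
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  t <- slope / se
  list(slope = slope, t = t, p = 2 * pt(-abs(t), n - 2))
}
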