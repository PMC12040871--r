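#' Per-unit resource and dimension shares
#'
#' For one year, category and allocation dimension, computes each unit's
#' resource share \eqn{h_i/H} (its fraction of all workers in scope), its
#' dimension share \eqn{p_i/P} (its fraction of the scope's population,
#' GDP or land area), and its density (workers per dimension unit: per
#' 10,000 persons for the population dimension, per unit of GDP for the
#' economy dimension, per km^2 for geography).
#'
#' @param panel A `workforce_panel`.
#' @param year Calendar year present in the panel.
#' @param category `"staff"` or `"health_professionals"`.
#' @param dimension `"population"`, `"gdp"` or `"area"`.
#' @param scope `"national"` or a region label.
#' @return A tibble with `unit`, `region`, `resource_share`,
#'   `dimension_share`, `density`; the share columns each sum to 1.
#' @export
unit_shares <- function(panel, year, category = "staff",
                        dimension = c("population", "gdp", "area"),
                        scope = "national") {
  stopifnot(inherits(panel, "workforce_panel"))
  category <- match.arg(category, c("staff", "health_professionals"))
  dimension <- match.arg(dimension)
  rows <- scope_rows(panel, scope)
  rows <- rows[rows$year == year, , drop = FALSE]
  if (nrow(rows) == 0) {
    hw_stop(paste0("no records for year ", year, " in scope '", scope, "'"),
            "hw_domain_error")
  }
  h <- rows[[category]]
  p <- switch(dimension, population = rows$population, gdp = rows$gdp,
              area = rows$area_km2)
  H <- sum(h)
  P <- sum(p)
  if (H <= 0) {
    hw_stop("all worker counts are zero in this scope; shares are undefined",
            "hw_degenerate_scope_error")
  }
  per <- if (dimension == "population") 1e4 else 1
  tibble::tibble(unit = rows$unit, region = rows$region,
                 resource_share = h / H, dimension_share = p / P,
                 density = h / p * per)
}

#' Build a Lorenz curve from unit shares
#'
#' Sorts units by density ascending (ties broken by unit name so the
#' vertex list is deterministic), cumulates the dimension and resource
#' shares, and prepends the origin. The resulting polyline runs from
#' (0, 0) to (1, 1) and lies on or below the diagonal; its departure from
#' the diagonal is what the Gini coefficient integrates.
#'
#' @param shares A tibble from [unit_shares()], or any data frame with
#'   `resource_share`, `dimension_share` and `density` columns.
#' @return A tibble of class `lorenz_curve` with cumulative coordinates
#'   `x` (dimension share) and `y` (resource share).
#' @export
lorenz_curve <- function(shares) {
  if (nrow(shares) < 1) hw_stop("need at least one unit", "hw_domain_error")
  if (any(shares$resource_share < 0) || any(shares$dimension_share < 0)) {
    hw_stop("negative share", "hw_domain_error")
  }
  ord <- order(shares$density, shares$unit %||% seq_len(nrow(shares)))
  s <- shares[ord, , drop = FALSE]
  out <- tibble::tibble(x = c(0, cumsum(s$dimension_share)),
                        y = c(0, cumsum(s$resource_share)))
  # guard against float drift at the endpoint
  out$x[nrow(out)] <- 1
  out$y[nrow(out)] <- 1
  class(out) <- c("lorenz_curve", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gini coefficient by trapezoid integration of a Lorenz curve
#'
#' Twice the area between the curve and the diagonal:
#' \deqn{G = 1 - \sum_k (x_k - x_{k-1})(y_k + y_{k-1}).}
#'
#' @param curve A [lorenz_curve()].
#' @return Gini coefficient in `[0, 1]`.
#' @examples
#' sh <- tibble::tibble(unit = c("a", "b", "c"), density = 1:3,
#'                      resource_share = c(1/6, 1/3, 1/2),
#'                      dimension_share = rep(1/3, 3))
#' gini_from_lorenz(lorenz_curve(sh))  # 0.2222
#' @export
gini_from_lorenz <- function(curve) {
  x <- curve$x
  y <- curve$y
  1 - sum(diff(x) * (y[-1] + y[-length(y)]))
}

#' Gini coefficient from weighted pairwise differences
#'
#' The mean-normalized, weight-generalized Gini
#' \deqn{G = \frac{\sum_i \sum_j w_i w_j |x_i - x_j|}{2\mu}, \qquad
#'       \mu = \sum_i w_i x_i,}
#' where `weights` are the dimension shares. With equal weights this
#' reduces to the classical estimator
#' \eqn{\sum_i\sum_j |x_i-x_j| / (2 N^2 \bar x)}. The mean normalization
#' makes G scale-free and confines it to `[0, 1)`; an unnormalized
#' pairwise sum would change under rescaling of the densities and is not
#' a usable inequality measure (see the methods vignette).
#'
#' @param densities Numeric density values.
#' @param weights Dimension-share weights; default equal. Normalized to
#'   sum to 1 internally.
#' @return Gini coefficient in `[0, 1)`.
#' @examples
#' gini_pairwise(c(1, 2, 3))  # 0.2222
#' @export
gini_pairwise <- function(densities, weights = NULL) {
  n <- length(densities)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (any(weights < 0)) hw_stop("negative weight", "hw_domain_error")
  weights <- weights / sum(weights)
  mu <- sum(weights * densities)
  if (mu <= 0) {
    hw_stop("mean density is zero; Gini undefined",
            "hw_degenerate_scope_error")
  }
  sum(outer(weights, weights) * abs(outer(densities, densities, "-"))) /
    (2 * mu)
}

#' Gini coefficient of a panel slice
#'
#' Convenience wrapper: builds shares with [unit_shares()] and integrates
#' the Lorenz curve.
#'
#' @inheritParams unit_shares
#' @return Gini coefficient.
#' @export
gini_index <- function(panel, year, category = "staff",
                       dimension = "population", scope = "national") {
  gini_from_lorenz(lorenz_curve(
    unit_shares(panel, year, category, dimension, scope)))
}

#' Gini coefficients across years, categories, dimensions and scopes
#'
#' Produces one row per (year, category, dimension, scope) combination,
#' the layout of a dimension-by-region Gini report table.
#'
#' @param panel A `workforce_panel`.
#' @param categories Worker categories to include.
#' @param dimensions Allocation dimensions to include.
#' @param scopes Scopes; defaults to national plus every region present.
#' @return A tibble with columns `year`, `category`, `dimension`,
#'   `scope`, `gini`.
#' @export
gini_table <- function(panel,
                       categories = c("staff", "health_professionals"),
                       dimensions = c("population", "gdp", "area"),
                       scopes = NULL) {
  stopifnot(inherits(panel, "workforce_panel"))
  if (is.null(scopes)) scopes <- c("national", sort(unique(panel$region)))
  grid <- expand.grid(year = sort(unique(panel$year)),
                      category = categories, dimension = dimensions,
                      scope = scopes, stringsAsFactors = FALSE)
  grid$gini <- vapply(seq_len(nrow(grid)), function(i) {
    gini_index(panel, grid$year[i], grid$category[i], grid$dimension[i],
               grid$scope[i])
  }, numeric(1))
  tibble::as_tibble(grid)
}
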