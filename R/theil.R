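#' Theil L index (mean log deviation) from unit shares
#'
#' \deqn{L = \sum_i \frac{p_i}{P}\,\ln\frac{X}{x_i},}
#' weighting log density ratios by dimension (population) shares, with
#' \eqn{X = H/P} the scope-wide density. Equivalently
#' \eqn{L = \ln X - \ln\chi}, the log of the arithmetic mean density over
#' its weighted geometric mean \eqn{\chi}; both forms are computed and
#' the identity is asserted internally. L is undefined when any unit with
#' positive weight has zero workers: the geometric mean collapses to 0
#' and the index diverges, so a classed error is raised instead.
#'
#' @param shares A tibble from [unit_shares()] (columns `resource_share`,
#'   `dimension_share`, `density`).
#' @return A list with `value`, `arithmetic_mean_density` and
#'   `geometric_mean_density`.
#' @export
theil_L <- function(shares) {
  w <- shares$dimension_share
  x <- shares$density
  keep <- w > 0
  if (any(x[keep] <= 0)) {
    hw_stop(paste0("Theil L is undefined: zero-worker unit(s) make the ",
                   "geometric mean density zero"),
            "hw_zero_worker_error")
  }
  X <- sum(w * x)                       # H/P in density units
  chi <- exp(sum(w[keep] * log(x[keep])))
  value <- sum(w[keep] * log(X / x[keep]))
  stopifnot(abs(value - log(X / chi)) < 1e-10 * max(1, abs(value)))
  list(value = value, arithmetic_mean_density = X,
       geometric_mean_density = chi)
}

#' Theil T index from unit shares
#'
#' \deqn{T = \sum_i \frac{h_i}{H}\,\ln\frac{h_i/H}{p_i/P},}
#' weighting log share ratios by resource shares. Terms with zero
#' resource share contribute zero (the \eqn{x\ln x \to 0} convention), so
#' T stays finite when some units have no workers; a unit with positive
#' workers but zero dimension weight is a domain error.
#'
#' @inheritParams theil_L
#' @return A list with `value` and `arithmetic_mean_density`.
#' @export
theil_T <- function(shares) {
  s <- shares$resource_share
  w <- shares$dimension_share
  if (any(s > 0 & w <= 0)) {
    hw_stop("unit with workers but zero dimension share", "hw_domain_error")
  }
  keep <- s > 0
  value <- sum(s[keep] * log(s[keep] / w[keep]))
  list(value = value,
       arithmetic_mean_density = sum(w * shares$density))
}

#' Theil index of a panel slice
#'
#' Convenience wrapper: builds population-dimension shares for one year
#' and scope and evaluates Theil T or L.
#'
#' @inheritParams unit_shares
#' @param index_kind `"T"` or `"L"`.
#' @param dimension Allocation dimension; population is the conventional
#'   choice for Theil workforce analysis and the default.
#' @return The index value (numeric scalar).
#' @export
theil_index <- function(panel, year, category = "staff",
                        index_kind = c("T", "L"),
                        dimension = "population", scope = "national") {
  index_kind <- match.arg(index_kind)
  sh <- unit_shares(panel, year, category, dimension, scope)
  if (index_kind == "T") theil_T(sh)$value else theil_L(sh)$value
}

#' Within-/between-region decomposition of a Theil index
#'
#' Splits the overall inter-unit index for one year into additive parts.
#' With groups g holding worker totals \eqn{H_g} and dimension totals
#' \eqn{P_g}:
#' \itemize{
#'   \item Theil T: within \eqn{= \sum_g (H_g/H)\,T_g}, between
#'     \eqn{= \sum_g (H_g/H)\ln\frac{H_g/H}{P_g/P}};
#'   \item Theil L: within \eqn{= \sum_g (P_g/P)\,L_g}, between
#'     \eqn{= \sum_g (P_g/P)\ln\frac{P_g/P}{H_g/H}}.
#' }
#' Within + between reproduces the pooled index exactly (up to float
#' round-off), and the percentage attribution is computed from the
#' unrounded components. When the overall index is 0 the percentages are
#' undefined and returned as `NA` with `degenerate = TRUE`.
#'
#' @inheritParams theil_index
#' @param grouping Column used to group units (default `"region"`).
#' @return A list with `overall`, `within`, `between`, `within_percent`,
#'   `between_percent`, `degenerate`, and a `groups` tibble holding each
#'   group's own index and its weight in the within term.
#' @export
theil_decompose <- function(panel, year, category = "staff",
                            index_kind = c("T", "L"),
                            dimension = "population", scope = "national",
                            grouping = "region") {
  index_kind <- match.arg(index_kind)
  sh <- unit_shares(panel, year, category, dimension, scope)
  grp_rows <- scope_rows(panel, scope)
  grp_rows <- grp_rows[grp_rows$year == year, , drop = FALSE]
  sh$group <- grp_rows[[grouping]][match(sh$unit, grp_rows$unit)]
  if (anyNA(sh$group)) hw_stop("grouping label missing for some units",
                               "hw_domain_error")

  labels <- sort(unique(sh$group))
  Hg <- vapply(labels, function(g) sum(sh$resource_share[sh$group == g]),
               numeric(1))
  Pg <- vapply(labels, function(g) sum(sh$dimension_share[sh$group == g]),
               numeric(1))
  if (any(Pg <= 0)) hw_stop("empty group in decomposition", "hw_domain_error")

  group_index <- vapply(labels, function(g) {
    sub <- sh[sh$group == g, , drop = FALSE]
    # renormalize shares within the group
    sub$resource_share <- sub$resource_share / sum(sub$resource_share)
    sub$dimension_share <- sub$dimension_share / sum(sub$dimension_share)
    if (index_kind == "T") theil_T(sub)$value else theil_L(sub)$value
  }, numeric(1))

  if (index_kind == "T") {
    weight <- Hg
    between <- sum(Hg[Hg > 0] * log(Hg[Hg > 0] / Pg[Hg > 0]))
  } else {
    weight <- Pg
    if (any(Hg <= 0)) {
      hw_stop("Theil L decomposition undefined: a group has zero workers",
              "hw_zero_worker_error")
    }
    between <- sum(Pg * log(Pg / Hg))
  }
  within <- sum(weight * group_index)
  overall <- if (index_kind == "T") theil_T(sh)$value else theil_L(sh)$value

  degenerate <- overall <= 0
  list(index_kind = index_kind,
       overall = overall, within = within, between = between,
       within_percent = if (degenerate) NA_real_ else 100 * within / overall,
       between_percent = if (degenerate) NA_real_ else 100 * between / overall,
       degenerate = degenerate,
       groups = tibble::tibble(group = labels, index = group_index,
                               weight = weight))
}

#' Theil indices and decomposition across all years and categories
#'
#' Produces two report tables: `indices`, with one row per (year,
#' category) holding the overall inter-unit Theil T and L plus each
#' region's own index; and `decomposition`, with one row per (year,
#' category, index kind) holding the overall index, within and between
#' components and their percentage attribution.
#'
#' @param panel A `workforce_panel`.
#' @param categories Worker categories to include.
#' @param dimension Allocation dimension (population by default).
#' @return A list of tibbles `indices` and `decomposition`.
#' @export
theil_table <- function(panel,
                        categories = c("staff", "health_professionals"),
                        dimension = "population") {
  stopifnot(inherits(panel, "workforce_panel"))
  years <- sort(unique(panel$year))
  regions <- sort(unique(panel$region))
  idx <- list()
  dec <- list()
  for (cat in categories) {
    for (yr in years) {
      row <- tibble::tibble(year = yr, category = cat)
      for (kind in c("T", "L")) {
        row[[paste0("theil_", kind, "_overall")]] <-
          theil_index(panel, yr, cat, kind, dimension)
        for (rg in regions) {
          row[[paste0("theil_", kind, "_", rg)]] <-
            theil_index(panel, yr, cat, kind, dimension, scope = rg)
        }
        d <- theil_decompose(panel, yr, cat, kind, dimension)
        dec[[length(dec) + 1]] <- tibble::tibble(
          year = yr, category = cat, index_kind = kind,
          overall = d$overall, within = d$within, between = d$between,
          within_percent = d$within_percent,
          between_percent = d$between_percent,
          degenerate = d$degenerate)
      }
      idx[[length(idx) + 1]] <- row
    }
  }
  list(indices = dplyr::bind_rows(idx),
       decomposition = dplyr::bind_rows(dec))
}
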