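test_that("Theil T and L match hand-derived two- and three-unit values", {
  sh2 <- shares_from_raw(h = c(8, 2), p = c(5, 5))
  expect_equal(theil_L(sh2)$value, 0.5 * log(0.5 / 0.8) + 0.5 * log(0.5 / 0.2),
               tolerance = 1e-12)
  expect_equal(round(theil_L(sh2)$value, 4), 0.2231)
  expect_equal(theil_T(sh2)$value, 0.8 * log(1.6) + 0.2 * log(0.4),
               tolerance = 1e-12)
  expect_equal(round(theil_T(sh2)$value, 4), 0.1927)

  sh3 <- shares_from_raw(h = c(1, 2, 3), p = c(2, 2, 2))
  expect_equal(round(theil_L(sh3)$value, 4), 0.0959)
  expect_equal(round(theil_T(sh3)$value, 4), 0.0872)

  equal <- shares_from_raw(h = c(3, 3, 3), p = c(1, 1, 1))
  expect_equal(theil_L(equal)$value, 0)
  expect_equal(theil_T(equal)$value, 0)
})

test_that("Theil L satisfies the geometric-mean identity", {
  set.seed(7)
  h <- rpois(12, 400) + 1
  p <- runif(12, 1e5, 1e6)
  res <- theil_L(shares_from_raw(h, p))
  expect_equal(res$value,
               log(res$arithmetic_mean_density /
                     res$geometric_mean_density),
               tolerance = 1e-12)
})

test_that("Theil from panel slices matches the raw-count loop oracle", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(3:31, 1)
    p <- round(runif(n, 1e5, 5e7))
    h <- rpois(n, lambda = runif(n, 50, 5000)) + 1
    panel <- make_panel(staff = h, population = p)
    expect_equal(theil_index(panel, 2023, index_kind = "T"),
                 oracle_theil_T(h, p), tolerance = 1e-12)
    expect_equal(theil_index(panel, 2023, index_kind = "L"),
                 oracle_theil_L(h, p), tolerance = 1e-12)
  }
})

test_that("within + between reproduces the overall index on random panels", {
  set.seed(55)
  for (i in 1:20) {
    cfg <- synthetic_config(
      n_units_per_region = c(a = sample(3:12, 1), b = sample(3:12, 1),
                             c = sample(3:12, 1)),
      mean_log_density = c(a = runif(1, -0.5, 0.5), b = runif(1, -0.5, 0.5),
                           c = runif(1, -0.5, 0.5)),
      sigma_within = runif(1, 0.05, 0.8),
      years = 2021, seed = sample.int(1e6, 1))
    panel <- generate_panel(cfg)
    for (kind in c("T", "L")) {
      d <- theil_decompose(panel, 2021, index_kind = kind)
      expect_equal(d$within + d$between, d$overall, tolerance = 1e-12)
      if (!d$degenerate) {
        expect_equal(d$within_percent + d$between_percent, 100,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("decomposition limits: worked two-region case and single group", {
  # two internally uniform regions, equal populations, densities 1 and 3
  panel <- make_panel(staff = c(100, 100, 300, 300),
                      population = rep(1e6, 4),
                      regions = c("lo", "lo", "hi", "hi"))
  d <- theil_decompose(panel, 2023, index_kind = "T")
  expect_equal(d$within, 0, tolerance = 1e-12)
  expect_equal(d$between, 0.25 * log(0.5) + 0.75 * log(1.5),
               tolerance = 1e-12)
  expect_equal(round(d$overall, 4), 0.1308)

  one <- theil_decompose(make_panel(staff = c(10, 20, 30)), 2023,
                         index_kind = "L")
  expect_equal(one$between, 0, tolerance = 1e-12)
  expect_equal(one$within, one$overall, tolerance = 1e-12)
})

test_that("zero-worker units break L but leave T finite", {
  panel <- generate_panel(synthetic_config(seed = 17))
  z <- inject_zero_unit(panel, "western_unit_03", 2022)
  expect_error(theil_index(z, 2022, index_kind = "L"),
               class = "hw_zero_worker_error")
  tval <- theil_index(z, 2022, index_kind = "T")
  expect_true(is.finite(tval) && tval >= 0)
  # other years are untouched
  expect_equal(theil_index(z, 2021, index_kind = "L"),
               theil_index(panel, 2021, index_kind = "L"))
})

test_that("T and L coincide to first order for near-equal densities", {
  # symmetric perturbation: odd moments vanish, so T - L is fourth order
  z <- seq(-1.95, 1.95, by = 0.1)
  x <- 1 + 0.01 * z
  w <- rep(1 / 40, 40)
  sh <- tibble::tibble(unit = sprintf("u%02d", 1:40), density = x,
                       dimension_share = w,
                       resource_share = w * x / sum(w * x))
  T <- theil_T(sh)$value
  L <- theil_L(sh)$value
  expect_lt(abs(T - L), 1e-4 * T)
})

test_that("theil_table carries the additivity into report rows", {
  panel <- generate_panel(synthetic_config(seed = 29))
  tt <- theil_table(panel)
  expect_equal(nrow(tt$indices), 10)        # 5 years x 2 categories
  expect_equal(nrow(tt$decomposition), 20)  # x 2 index kinds
  expect_equal(tt$decomposition$within + tt$decomposition$between,
               tt$decomposition$overall, tolerance = 1e-12)

  scaled <- panel
  scaled$staff <- scaled$staff * 10
  scaled$health_professionals <- scaled$health_professionals * 10
  tt2 <- theil_table(scaled)
  expect_equal(tt2$indices$theil_T_overall, tt$indices$theil_T_overall,
               tolerance = 1e-12)
  expect_equal(tt2$indices$theil_L_overall, tt$indices$theil_L_overall,
               tolerance = 1e-12)
})
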