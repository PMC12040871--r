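test_that("unit shares normalize and respect the chosen dimension", {
  panel <- make_panel(staff = c(8, 2), population = c(1e6, 1e6),
                      area = c(5e4, 2e5))
  sh <- unit_shares(panel, 2023, dimension = "population")
  expect_equal(sh$resource_share, c(0.8, 0.2))
  expect_equal(sh$dimension_share, c(0.5, 0.5))
  sha <- unit_shares(panel, 2023, dimension = "area")
  expect_equal(sha$dimension_share, c(0.2, 0.8))
  expect_equal(sum(sha$resource_share), 1)

  zero <- make_panel(staff = c(0, 0))
  expect_error(unit_shares(zero, 2023), class = "hw_degenerate_scope_error")
})

test_that("Lorenz vertices match hand-computed cumulative sums", {
  sh <- shares_from_raw(h = c(1, 2, 3), p = c(1, 1, 1))
  cv <- lorenz_curve(sh)
  expect_equal(cv$x, c(0, 1/3, 2/3, 1))
  expect_equal(cv$y, c(0, 1/6, 1/2, 1))
  expect_true(all(diff(cv$x) >= 0) && all(diff(cv$y) >= 0))
  expect_true(all(cv$y <= cv$x + 1e-12))

  # total concentration in one of two equal-weight units
  conc <- lorenz_curve(shares_from_raw(h = c(0, 5), p = c(1, 1)))
  expect_equal(conc$x, c(0, 0.5, 1))
  expect_equal(conc$y, c(0, 0, 1))
  expect_equal(gini_from_lorenz(conc), 0.5)
})

test_that("Gini matches hand-derived values and the pairwise form", {
  expect_equal(gini_from_lorenz(lorenz_curve(
    shares_from_raw(c(1, 2, 3), c(1, 1, 1)))), 2/9, tolerance = 1e-12)
  expect_equal(gini_pairwise(c(1, 2, 3)), 2/9, tolerance = 1e-12)
  expect_equal(gini_pairwise(c(0, 2)), 0.5)
  expect_equal(gini_pairwise(rep(4, 6)), 0)
  expect_error(gini_pairwise(c(0, 0)), class = "hw_degenerate_scope_error")
})

test_that("Lorenz and pairwise Gini agree to 1e-12 on random weighted cases", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(2:25, 1)
    x <- rlnorm(n, sdlog = runif(1, 0.1, 1.2))
    w <- runif(n); w <- w / sum(w)
    sh <- tibble::tibble(unit = sprintf("u%02d", seq_len(n)),
                         density = x, dimension_share = w,
                         resource_share = w * x / sum(w * x))
    expect_equal(gini_from_lorenz(lorenz_curve(sh)), gini_pairwise(x, w),
                 tolerance = 1e-12)
  }
})

test_that("Gini obeys transfer, scale and replication principles", {
  panel <- make_panel(staff = c(100, 200, 400, 800))
  g0 <- gini_index(panel, 2023)

  # Pigou-Dalton: richer-to-poorer transfer without rank reversal
  transfer <- make_panel(staff = c(150, 200, 400, 750))
  expect_lt(gini_index(transfer, 2023), g0)

  # scale invariance in resource and dimension
  scaled <- make_panel(staff = c(100, 200, 400, 800) * 10,
                       population = rep(1e7, 4) * 3)
  expect_equal(gini_index(scaled, 2023), g0, tolerance = 1e-12)

  # replication invariance: duplicating every unit leaves G unchanged
  x <- c(1, 3, 7, 9); w <- rep(0.25, 4)
  expect_equal(gini_pairwise(c(x, x), rep(w / 2, 2)), gini_pairwise(x, w),
               tolerance = 1e-12)
})

test_that("gini_table covers the full grid and is scale invariant", {
  panel <- generate_panel(synthetic_config(seed = 13))
  gt <- gini_table(panel)
  expect_equal(nrow(gt), 5 * 2 * 3 * 4)  # years x categories x dims x scopes
  expect_true(all(gt$gini >= 0 & gt$gini <= 1))

  scaled <- panel
  scaled$staff <- scaled$staff * 10
  scaled$health_professionals <- scaled$health_professionals * 10
  gt2 <- gini_table(scaled)
  expect_equal(gt2$gini, gt$gini, tolerance = 1e-12)

  flat <- generate_panel(synthetic_config(
    sigma_within = 0,
    mean_log_density = c(eastern = 0.2, central = 0.2, western = 0.2),
    population_range = c(1e7, 1e7), annual_density_growth = 0))
  gflat <- gini_table(flat, dimensions = "population")
  expect_true(all(abs(gflat$gini) < 1e-12))
})
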