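test_that("the two-part distance is a weighted sum of absolute differences", {
  a <- list(prop_rising = 0.530, median_rising = 0.45)
  expect_equal(onglide_distance(a, a)$total, 0)
  b <- list(prop_rising = 0.500, median_rising = 0.45)
  d <- onglide_distance(a, b)
  expect_equal(d$total, 0.030)
  expect_equal(d$prop_component, 0.030)
  expect_equal(d$median_component, 0)
  b2 <- list(prop_rising = 0.500, median_rising = 0.55)
  expect_equal(onglide_distance(a, b2)$total, 0.030 + 0.10)
  expect_equal(onglide_distance(a, b2, weights = c(1, 0))$total, 0.030)
  expect_equal(onglide_distance(a, b2, weights = c(0, 2))$total, 0.20)
})

test_that("an undefined median is penalised, not silently ignored", {
  a <- list(prop_rising = 0.5, median_rising = 0.45)
  b <- list(prop_rising = 0.5, median_rising = NA_real_)
  expect_warning(d <- onglide_distance(a, b), "median")
  expect_gte(d$total, 1e3)
  expect_silent(onglide_distance(a, b, weights = c(1, 0)))
})

test_that("inverting the rising probability is exact at symmetry and monotone", {
  expect_equal(invert_rising_probability(0.5), 0)
  props <- c(0.2, 0.4, 0.6, 0.8, 0.95)
  ks <- vapply(props, invert_rising_probability, numeric(1))
  expect_true(all(diff(ks) > 0))
  expect_error(invert_rising_probability(0.999999), "achievable")
})

test_that("inversion recovers the tilt that generated a stationary proportion", {
  for (k_true in c(-2, 0.5, 4)) {
    p <- rising_probability(landscape("cubic_tilt", k_true))
    expect_equal(invert_rising_probability(p), k_true, tolerance = 1e-9)
  }
})

test_that("quadrature-method grid fit recovers oracle targets exactly", {
  for (k_true in c(-1.5, 0, 2.5)) {
    ls <- landscape("cubic_tilt", k_true)
    d <- data.frame(onglide_norm = c(-1, 1)) # placeholder records
    # feed the oracle's own statistics as the observation
    obs <- list(prop_rising = rising_probability(ls),
                median_rising = rising_median(ls))
    grid <- seq(k_true - 2, k_true + 2, by = 0.1)
    stats_grid <- onglide:::precompute_grid_stats(grid, 1, "quadrature",
                                                  1, 1, 0.005, 2000,
                                                  c(-1, 1), 1)
    tot <- mapply(function(p, m)
      onglide_distance(obs, list(prop_rising = p, median_rising = m))$total,
      stats_grid$prop, stats_grid$median)
    expect_equal(grid[which.min(tot)], k_true, tolerance = 1e-9)
  }
})

test_that("formula interface fits one tilt per stratum and ties break to
           the smallest |k|", {
  d <- generate_from_model(c(left = -2, right = 2), n_per_condition = 600,
                           seed = 9)
  fit <- landscape_fit(onglide_norm ~ condition, d,
                       grid = seq(-4, 4, by = 0.5), method = "quadrature")
  expect_s3_class(fit, "landscape_fit")
  expect_named(coef(fit), c("left", "right"))
  expect_lt(coef(fit)[["left"]], 0)
  expect_gt(coef(fit)[["right"]], 0)
  s <- summary(fit)
  expect_equal(nrow(s), 2L)
  expect_true(all(s$distance <=
    vapply(fit$fits, function(f) min(f$distance$total), numeric(1)) + 1e-12))
  # symmetric targets: the most parsimonious tilt (k = 0) wins a tie
  d0 <- data.frame(onglide_norm = c(rep(-0.45, 50), rep(0.45, 50)))
  fit0 <- landscape_fit(onglide_norm ~ 1, d0, grid = seq(-1, 1, by = 0.25),
                        weights = c(1, 0), method = "quadrature")
  expect_equal(unname(coef(fit0)), 0)
})

test_that("simulation fit agrees with the deterministic inversion", {
  # self-consistency: on proportion-only targets the stochastic grid search
  # must land within one grid step of the quadrature inverse
  obs_prop <- 0.781
  grid <- seq(2.6, 4.6, by = 0.1)
  d <- data.frame(onglide_norm = c(rep(-1, 1000 - 781), rep(1, 781)))
  fit <- landscape_fit(onglide_norm ~ 1, d, grid = grid, replicates = 4,
                       nsim = 2000, weights = c(1, 0), seed = 31)
  k_quad <- invert_rising_probability(obs_prop, grid)
  expect_lte(abs(coef(fit)[[1]] - k_quad), 0.2)
})

test_that("fit methods expose predictions, residuals and simulations", {
  d <- generate_from_model(c(broad = 0.3, narrow = 3.3), n_per_condition = 800,
                           seed = 13)
  fit <- landscape_fit(onglide_norm ~ condition, d,
                       grid = seq(-1, 5, by = 0.2), method = "quadrature")
  pr <- predict(fit, type = "prob")
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(unname(pr["narrow"] > pr["broad"]), TRUE)
  med <- predict(fit, type = "median")
  expect_true(all(med > 0))
  r <- residuals(fit)
  expect_equal(nrow(r), 2L)
  expect_true(all(abs(r$prop_residual) < 0.1))
  sims <- simulate(fit, nsim = 300, seed = 2)
  expect_named(sims, names(coef(fit)))
  expect_length(sims$broad, 300)
  expect_identical(fitted(fit), predict(fit, type = "prob"))
  expect_output(print(fit), "tilt fit")
  expect_output(print(summary(fit)), "k_hat")
})

test_that("fit validates its inputs", {
  d <- data.frame(onglide_norm = c(-1, 1))
  expect_error(landscape_fit(onglide_norm ~ 1, d, grid = numeric(0)), "grid")
  expect_error(landscape_fit(~1, d), "response")
})
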