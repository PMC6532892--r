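test_that("potential evaluates each family exactly", {
  expect_identical(potential(landscape("cubic_tilt", 0), 0), 0)
  # 18 * 0.5^4 - 7.5 * 0.25
  expect_equal(potential(landscape("cubic_tilt", 0), 0.5), -0.75)
  expect_equal(potential(landscape("linear_tilt", 0), 1), 0)
  expect_equal(potential(landscape("intro_linear"), -0.5), 0.0625)
  expect_equal(potential(landscape("cubic_tilt", 2), c(0.5, -0.5)),
               c(-0.75 - 2 * 0.125, -0.75 + 2 * 0.125))
  expect_error(potential(landscape("cubic_tilt", 0), Inf), "finite")
})

test_that("force evaluates each family exactly", {
  expect_identical(force(landscape("cubic_tilt", 17), 0), 0)
  expect_equal(force(landscape("cubic_tilt", 0), 0.5), -1.5)
  expect_equal(force(landscape("intro_linear"), -0.5), 0.25)
  expect_equal(force(landscape("linear_tilt", 3), 0), 3)
})

test_that("force is the negative derivative of the potential everywhere", {
  h <- 1e-5
  xs <- seq(-2, 2, by = 0.1)
  for (fam in c("intro_linear", "linear_tilt", "cubic_tilt"))
    for (k in c(-10, -3, 0, 0.3, 5.4, 10)) {
      ls <- landscape(fam, k)
      num <- -(potential(ls, xs + h) - potential(ls, xs - h)) / (2 * h)
      expect_equal(force(ls, xs), num, tolerance = 1e-6,
                   ignore_attr = TRUE)
    }
})

test_that("fixed points are roots of the force and correctly classified", {
  fp <- fixed_points(landscape("cubic_tilt", 0))
  expect_equal(fp$location, c(-sqrt(5 / 24), 0, sqrt(5 / 24)))
  expect_equal(fp$kind, c("attractor", "repeller", "attractor"))

  fp2 <- fixed_points(landscape("linear_tilt", 0))
  expect_equal(fp2$location, c(-1 / sqrt(2), 0, 1 / sqrt(2)),
               tolerance = 1e-9)
  expect_equal(fp2$kind, c("attractor", "repeller", "attractor"))

  for (k in seq(-10, 10, by = 2.5)) {
    fp <- fixed_points(landscape("cubic_tilt", k))
    expect_equal(nrow(fp), 3L)
    expect_lt(max(abs(force(landscape("cubic_tilt", k), fp$location))), 1e-9)
    att <- fp[fp$kind == "attractor", ]
    expect_equal(sort(sign(att$location)), c(-1, 1)) # one per side, always
  }
})

test_that("positive tilt deepens the right attractor", {
  for (k in c(0.5, 3, 6, 10)) {
    fp <- fixed_points(landscape("cubic_tilt", k))
    att <- fp[fp$kind == "attractor", ]
    expect_lt(att$potential[att$location > 0], att$potential[att$location < 0])
  }
  fp0 <- fixed_points(landscape("cubic_tilt", 0))
  att0 <- fp0[fp0$kind == "attractor", ]
  expect_equal(att0$potential[1], att0$potential[2])
})

test_that("the tilted double well loses an attractor at k_c = 4/(3 sqrt 6)", {
  k_c <- 4 / (3 * sqrt(6))
  expect_equal(attractor_count(landscape("linear_tilt", 0))$k_critical, k_c)
  expect_equal(attractor_count(landscape("linear_tilt", 0))$n_attractors, 2L)
  expect_equal(attractor_count(landscape("linear_tilt", 2))$n_attractors, 1L)
  expect_equal(attractor_count(landscape("linear_tilt", k_c + 1e-6))$n_attractors, 1L)
  expect_equal(attractor_count(landscape("linear_tilt", -k_c + 1e-6))$n_attractors, 2L)
  expect_equal(attractor_count(landscape("cubic_tilt", 99))$n_attractors, 2L)
})

test_that("unit-step iteration reproduces the worked example exactly", {
  ls <- landscape("intro_linear")
  expect_identical(iterate_map(ls, -0.5, 2), c(-0.5, -0.25, -0.125))
  expect_identical(iterate_map(ls, 0.3, 1), c(0.3, 0.15))
  expect_identical(iterate_map(ls, 0, 5), rep(0, 6))
})

test_that("landscape outputs respect the mirror symmetry k -> -k, x -> -x", {
  xs <- seq(-2, 2, by = 0.25)
  for (fam in c("linear_tilt", "cubic_tilt"))
    for (k in c(0.3, 3.3, 5.4)) {
      expect_equal(potential(landscape(fam, k), xs),
                   potential(landscape(fam, -k), -xs))
      expect_equal(force(landscape(fam, k), xs),
                   -force(landscape(fam, -k), -xs))
      expect_equal(fixed_points(landscape(fam, k))$location,
                   rev(-fixed_points(landscape(fam, -k))$location),
                   tolerance = 1e-9)
    }
})

test_that("landscape validates its inputs", {
  expect_error(landscape("cubic_tilt", 0, sigma = 0), "positive")
  expect_error(landscape("cubic_tilt", NA), "finite")
  expect_error(potential(list(), 0), "landscape")
})
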