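make_series <- function(t, a, b, uv) {
  deformation_series(data.frame(t_s = t, a_um = a, b_um = b, uv_on = uv))
}

test_that("series validation rejects unsorted times, bad axes, and inconsistent UV flags", {
  expect_error(make_series(c(0, 2, 1), rep(2, 3), rep(1, 3), c(0, 0, 1)),
               "strictly increasing")
  expect_error(make_series(0:2, c(2, 1, 2), c(1, 2, 1), c(0, 0, 1)),
               "a >= b")
  expect_error(make_series(0:2, rep(2, 3), rep(1, 3), c(0, 1, 0)),
               "non-decreasing")
  s <- make_series(0:3, rep(2, 4), rep(1, 4), c(0, 0, 1, 1))
  expect_equal(attr(s, "uv_onset_time"), 2)
})

test_that("per-frame area/volume uses the prolate closed forms", {
  s <- make_series(0:2, rep(1, 3), rep(1, 3), c(0, 0, 1))
  av <- area_volume_series(s)
  expect_equal(av$A_um2, rep(4 * pi, 3))
  expect_equal(av$aspect, rep(1, 3))
  s2 <- make_series(0, 2, 1, 0)
  expect_equal(area_volume_series(s2)$A_um2,
               spheroid_area_quadrature(2, 1), tolerance = 1e-8)
})

test_that("maximal deformation picks the plateau frame with earliest-time tie-break", {
  # monotone saturating ramp: last pre-UV frame wins
  t <- seq(0, 10, 0.5)
  r <- 1 + 0.05 * (1 - exp(-t / 1.5))
  s <- make_series(t, r, rep(1, length(t)), t >= 7)
  expect_equal(max_deformation(s, "pre_uv")$t_s, 6.5)
  # flat series: first frame of the window
  sf <- make_series(t, rep(1.2, length(t)), rep(1, length(t)), t >= 7)
  expect_equal(max_deformation(sf, "pre_uv")$t_s, 0)
  expect_equal(max_deformation(sf, "post_uv")$t_s, 7)
  expect_error(max_deformation(make_series(0:2, rep(2, 3), rep(1, 3),
                                           rep(0, 3)), "post_uv"),
               "no frames")
})

test_that("relative area increase is zero at identity and matches printed magnitudes", {
  expect_identical(relative_area_increase(100, 100), 0)
  A <- 137.2
  expect_equal(relative_area_increase(A, 1.046 * A), 0.046, tolerance = 1e-12)
  expect_equal(relative_area_increase(A, 1.051 * A), 0.051, tolerance = 1e-12)
  expect_error(relative_area_increase(0, 1), "positive")
  # multiplicative composition of increments
  d1 <- relative_area_increase(A, 1.02 * A)
  d2 <- relative_area_increase(1.02 * A, 1.02 * 1.03 * A)
  expect_equal((1 + d1) * (1 + d2) - 1,
               relative_area_increase(A, 1.02 * 1.03 * A), tolerance = 1e-12)
})

test_that("analyze_series extracts baseline and UV areas; degenerate series handled", {
  # sphere-only series: no area change, nu exactly 1
  t <- seq(0, 20, 1)
  s <- make_series(t, rep(5, length(t)), rep(5, length(t)), t >= 7)
  res <- analyze_series(s)
  expect_identical(res$delta_A_rel, 0)
  expect_equal(res$nu_baseline, 1, tolerance = 1e-12)
  # no UV frames -> error
  expect_error(analyze_series(make_series(t, rep(5, 21), rep(5, 21),
                                          rep(0, 21))), "no frames")
})

test_that("population summary gives mean and n-1 SEM", {
  s <- summarize_population(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3), tolerance = 1e-9)
  expect_equal(summarize_population(rep(4.2, 10))$sem, 0)
  expect_error(summarize_population(1), "at least 2")
  # sampling design of a 30-vesicle cohort: mean within 3 SEM of truth
  set.seed(99)
  draws <- rnorm(30, mean = 0.043, sd = 0.0022)
  ps <- summarize_population(draws)
  expect_lt(abs(ps$mean - 0.043), 3 * ps$sem)
})
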