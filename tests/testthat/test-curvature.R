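test_that("neck condition collapses to the mean inverse radius without the nonlocal term", {
  r <- neck_curvature(R_alpha = 1, R_beta = 1, kappa_ratio = 0)
  expect_equal(r$m, 1)
  expect_identical(r$m_nlo, 0)
  expect_equal(r$m_bar, sqrt(2))
  r2 <- neck_curvature(R_alpha = 10, R_beta = 1.5, kappa_ratio = 0)
  expect_equal(r2$m, (0.1 + 1 / 1.5) / 2, tolerance = 1e-12)
  expect_equal(1 / r2$m, 2.61, tolerance = 1e-3)  # the micron scale of GUV buds
})

test_that("nonlocal term matches the symbolic evaluation and is never positive", {
  r <- neck_curvature(R_alpha = 1, R_beta = 1, kappa_ratio = 1)
  expect_equal(r$m, 1 + pi * (2 - sqrt(2)) / 2, tolerance = 1e-12)
  set.seed(7)
  for (i in 1:50) {
    Rb <- runif(1, 0.1, 5); Ra <- Rb * runif(1, 1, 10)
    kr <- runif(1, 0, 2)
    res <- neck_curvature(R_alpha = Ra, R_beta = Rb, kappa_ratio = kr)
    expect_lte(res$m_nlo, 0)
    expect_equal(res$m_eff, res$m + res$m_nlo, tolerance = 1e-12)
    expect_equal(res$m, neck_m_reference(Ra, Rb, kr), tolerance = 1e-12)
  }
  # m_nlo = 0 iff kappa_ratio = 0
  expect_identical(neck_curvature(R_alpha = 3, R_beta = 1, kappa_ratio = 0)$m_nlo, 0)
  expect_lt(neck_curvature(R_alpha = 3, R_beta = 1, kappa_ratio = 1e-6)$m_nlo, 0)
})

test_that("local curvature increases affinely with the rigidity ratio", {
  shape <- budded_shape(8, 2)
  krs <- c(0, 0.5, 1, 1.5, 2)
  ms <- vapply(krs, function(k) neck_curvature(shape, k)$m, numeric(1))
  expect_true(all(diff(ms) > 0))
  # affine: second differences vanish
  expect_equal(diff(diff(ms)), rep(0, 3), tolerance = 1e-12)
})

test_that("curvature is scale covariant", {
  base <- neck_curvature(R_alpha = 6, R_beta = 1.2, kappa_ratio = 1.3)
  for (lam in c(0.5, 2, 10)) {
    sc <- neck_curvature(R_alpha = 6 * lam, R_beta = 1.2 * lam,
                         kappa_ratio = 1.3)
    expect_equal(sc$m, base$m / lam, tolerance = 1e-12)
    expect_equal(sc$m_bar, base$m_bar, tolerance = 1e-12)
  }
})

test_that("limit-shape line has the analytic equal-sphere endpoint and diverges for small buds", {
  ln <- limit_shape_line(0, x_grid = c(0.01, 0.5, 1))
  eq <- ln[which.min(abs(ln$x - 1)), ]
  expect_equal(eq$nu, nu_equal_spheres, tolerance = 1e-9)
  expect_equal(eq$m_bar, sqrt(2), tolerance = 1e-9)
  small <- ln[which.min(ln$x), ]
  expect_gt(small$m_bar, 10)
  expect_gt(small$nu, 0.999)
  # nonlocal term raises the line everywhere
  g <- seq(0.1, 1, length.out = 20)
  l0 <- limit_shape_line(0, g); l1 <- limit_shape_line(1, g)
  expect_true(all(l1$m_bar > l0$m_bar))
  # points sorted by nu, nu within the two-sphere band
  expect_true(all(diff(l0$nu) >= 0))
  expect_true(all(l0$nu > nu_equal_spheres - 1e-9 & l0$nu <= 1))
  expect_error(limit_shape_line(0, x_grid = 0.5), "at least 2")
  expect_error(limit_shape_line(0, x_grid = c(0, 0.5)), "\\(0, 1\\]")
})

test_that("limit line is independent of the internal normalisation", {
  # scale invariance: building shapes at a different mother radius gives the
  # same (nu, m_bar) curve
  g <- c(0.2, 0.5, 0.9)
  ln <- limit_shape_line(1.5, g)
  for (i in seq_along(g)) {
    cur <- neck_curvature(R_alpha = 23, R_beta = 23 * g[i], kappa_ratio = 1.5)
    expect_equal(cur$m_bar, ln$m_bar[ln$x == g[i]], tolerance = 1e-12)
  }
})

test_that("inverting the limit line round-trips through the forward map", {
  expect_equal(invert_limit_line(nu_equal_spheres + 1e-9), 1, tolerance = 1e-4)
  for (nu in c(0.72, 0.85, 0.95, 0.999)) {
    x <- invert_limit_line(nu)
    nu_back <- two_sphere_geometry(R_alpha = 1, R_beta = x)$nu
    expect_lt(abs(nu_back - nu), 1e-10)
  }
  expect_error(invert_limit_line(0.5), "outside")
  expect_error(invert_limit_line(1.0), "outside")
})

test_that("morphology classification separates the diagram at the limit line", {
  nu <- nu_equal_spheres + 1e-6
  expect_identical(classify_morphology(nu, 1.6, kappa_ratio = 0),
                   "above_limit_line")
  expect_identical(classify_morphology(nu, 1.0, kappa_ratio = 0),
                   "below_limit_line")
  # self-consistency: points produced by the line are on the line
  ln <- limit_shape_line(0.7, x_grid = c(0.3, 0.6, 0.95))
  for (i in seq_len(nrow(ln))) {
    expect_identical(
      classify_morphology(ln$nu[i], ln$m_bar[i], kappa_ratio = 0.7),
      "on_limit_line")
  }
})

test_that("pathway classification distinguishes area growth, curvature growth, and both", {
  expect_identical(pathway_trajectory(c(0.99, 0.95), c(1, 1)),
                   "area_increase_only")
  expect_identical(pathway_trajectory(c(0.95, 0.95), c(1, 2)),
                   "curvature_only")
  expect_identical(pathway_trajectory(c(0.99, 0.93), c(1, 1.8)), "both")
  expect_error(pathway_trajectory(0.99, 1), "at least 2")
  expect_warning(out <- pathway_trajectory(c(0.99, 0.99), c(1, 1)),
                 "no pathway")
  expect_true(is.na(out))
})
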