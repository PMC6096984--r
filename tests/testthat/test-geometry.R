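test_that("spheroid area matches the closed form in the sphere limit and rejects bad axes", {
  expect_equal(spheroid_area(a = 1, b = 1), 4 * pi, tolerance = 1e-12)
  # sphere limit over a log grid of radii, and continuity across the
  # series branch at a/b - 1 = 1e-8
  for (R in 10^seq(-1, 2, length.out = 7)) {
    expect_equal(spheroid_area(a = R, b = R), 4 * pi * R^2,
                 tolerance = 1e-10)
  }
  just_above <- spheroid_area(a = 1 + 2e-8, b = 1)
  just_below <- spheroid_area(a = 1 + 5e-9, b = 1)
  expect_lt(abs(just_above - just_below) / (4 * pi), 1e-7)
  expect_error(spheroid_area(a = 2, b = 2.0000001), "mixed up")
  expect_error(spheroid_shape(1, 0), "positive")
})

test_that("spheroid area agrees with the quadrature oracle across aspect ratios", {
  expect_equal(spheroid_area(a = 2, b = 1), 21.4784, tolerance = 1e-5)
  for (r in c(1.001, 1.5, 2, 3, 5, 10)) {
    closed <- spheroid_area(a = r, b = 1)
    quad <- spheroid_area_quadrature(r, 1)
    expect_lt(abs(closed - quad) / quad, 1e-8)
  }
})

test_that("spheroid volume is the closed form", {
  expect_equal(spheroid_volume(a = 1, b = 1), 4 * pi / 3)
  expect_equal(spheroid_volume(a = 2, b = 1), 8 * pi / 3)
  expect_equal(spheroid_volume(a = 3, b = 2), 16 * pi)
})

test_that("reduced volume is 1 for spheres, analytic for two equal spheres, and guarded above 1", {
  expect_equal(reduced_volume(4 * pi, 4 * pi / 3), 1, tolerance = 1e-12)
  expect_equal(reduced_volume(8 * pi, 8 * pi / 3), nu_equal_spheres,
               tolerance = 1e-12)
  # compose the spheroid oracles
  expect_equal(reduced_volume(spheroid_area(a = 2, b = 1),
                              spheroid_volume(a = 2, b = 1)),
               0.895, tolerance = 1e-3)
  expect_error(reduced_volume(10, 100), "> 1")
  # clip within tolerance
  A <- 4 * pi
  expect_identical(reduced_volume(A, (1 + 5e-10) * 4 * pi / 3), 1)
})

test_that("vesicle size is the equivalent-sphere radius", {
  expect_equal(vesicle_size(4 * pi), 1)
  expect_equal(vesicle_size(8 * pi), sqrt(2))
  expect_equal(vesicle_size(100), sqrt(100 / (4 * pi)))
  expect_error(vesicle_size(-1), "positive")
})

test_that("two-sphere geometry is scale invariant and monotone in the bud radius", {
  g <- two_sphere_geometry(R_alpha = 1, R_beta = 1)
  expect_equal(g$A, 8 * pi)
  expect_equal(g$V, 8 * pi / 3)
  expect_equal(g$nu, nu_equal_spheres, tolerance = 1e-12)
  # vanishing bud -> sphere
  expect_equal(two_sphere_geometry(R_alpha = 1, R_beta = 1e-7)$nu, 1,
               tolerance = 1e-9)
  base <- two_sphere_geometry(R_alpha = 10, R_beta = 1.5)
  for (lam in c(0.1, 3, 42)) {
    sc <- two_sphere_geometry(R_alpha = 10 * lam, R_beta = 1.5 * lam)
    expect_equal(sc$nu, base$nu, tolerance = 1e-12)
    expect_equal(sc$R_ve, base$R_ve * lam, tolerance = 1e-12)
  }
  # nu strictly decreasing in R_beta at fixed R_alpha
  Rb <- seq(0.01, 1, length.out = 200)
  nus <- vapply(Rb, function(r) two_sphere_geometry(R_alpha = 1, R_beta = r)$nu,
                numeric(1))
  expect_true(all(diff(nus) < 0))
  expect_equal(nus[length(nus)], nu_equal_spheres, tolerance = 1e-12)
})

test_that("spheroid_from_area_volume inverts (area, volume) to 1e-9", {
  s <- spheroid_from_area_volume(4 * pi, 4 * pi / 3)
  expect_equal(c(s$a, s$b), c(1, 1), tolerance = 1e-9)
  s2 <- spheroid_from_area_volume(spheroid_area(a = 2, b = 1), 8 * pi / 3)
  expect_equal(c(s2$a, s2$b), c(2, 1), tolerance = 1e-8)
  expect_error(spheroid_from_area_volume(10, 100), "> 1")
  # round trip on random admissible shapes
  set.seed(42)
  for (i in 1:20) {
    a <- runif(1, 1, 20); b <- runif(1, 0.2, 1) * a
    A <- spheroid_area(a = a, b = b); V <- spheroid_volume(a = a, b = b)
    inv <- spheroid_from_area_volume(A, V)
    expect_lt(abs(inv$a - a) / a, 1e-9)
    expect_lt(abs(inv$b - b) / b, 1e-9)
  }
})
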