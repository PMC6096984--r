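test_that("generators are deterministic in the seed and leave the RNG stream alone", {
  p1 <- gen_budded_population(n = 12, m_true = 0.4, seed = 101)
  p2 <- gen_budded_population(n = 12, m_true = 0.4, seed = 101)
  p3 <- gen_budded_population(n = 12, m_true = 0.4, seed = 102)
  expect_identical(p1$shapes, p2$shapes)
  expect_false(isTRUE(all.equal(p1$shapes$R_alpha_um, p3$shapes$R_alpha_um)))
  # the caller's RNG state is untouched
  set.seed(1); before <- .Random.seed
  invisible(gen_budded_population(n = 3, m_true = 0.4, seed = 55))
  expect_identical(.Random.seed, before)
  expect_error(gen_budded_population(n = 3, m_true = 0.4), "seed")
})

test_that("generated buds satisfy the neck condition exactly before noise", {
  # closed form at kappa_ratio = 0: R_beta = 1 / (2 m - 1/R_alpha)
  pop <- gen_budded_population(n = 4, m_true = 0.4, kappa_ratio = 0,
                               R_alpha_sdlog = 0, R_alpha_median = 10,
                               radius_noise = 0, seed = 1)
  expect_equal(pop$shapes$R_beta_um, rep(1 / 0.7, 4), tolerance = 1e-10)
  # general ratios: residual of the neck condition below 1e-10
  for (kr in c(0.5, 2)) {
    p <- gen_budded_population(n = 6, m_true = 0.35, kappa_ratio = kr,
                               radius_noise = 0, seed = 33)
    m <- vapply(seq_len(6), function(i)
      neck_curvature(budded_shape(p$shapes$R_alpha_um[i],
                                  p$shapes$R_beta_um[i]), kr)$m, numeric(1))
    expect_lt(max(abs(m - 0.35)), 1e-10)
  }
})

test_that("inadmissible curvature scales are rejected, not clamped", {
  # m_true = 0.01 1/um cannot close a neck on ~7.5 um vesicles
  expect_error(
    suppressMessages(gen_budded_population(n = 5, m_true = 0.01, seed = 2,
                                           max_tries = 50L)),
    "m_true too small")
})

test_that("deformation generator conserves volume and hits its plateau and area targets", {
  s <- gen_deformation_series(R0 = 10, r_max = 1.05, delta_A_max = 0.046,
                              frame_noise = 0)
  av <- area_volume_series(s)
  expect_lt(diff(range(av$V_um3)) / mean(av$V_um3), 1e-9)
  # pre-UV plateau reaches the configured aspect ratio within 0.1%
  pre_max <- max_deformation(s, "pre_uv")
  expect_lt(abs(pre_max$a_um / pre_max$b_um - 1.05) / 1.05, 1e-3)
  # final area equals (1 + delta_A_max) x baseline
  res <- analyze_series(s)
  expect_equal(res$delta_A_rel, 0.046, tolerance = 1e-9)
  # degenerate settings
  s0 <- gen_deformation_series(delta_A_max = 0, frame_noise = 0)
  expect_equal(analyze_series(s0)$delta_A_rel, 0, tolerance = 1e-12)
  sph <- gen_deformation_series(r_max = 1, delta_A_max = 0, frame_noise = 0)
  expect_equal(analyze_series(sph)$nu_baseline, 1, tolerance = 1e-12)
  expect_error(gen_deformation_series(frame_noise = 0.01), "seed")
  expect_warning(gen_deformation_series(t_uv = 1, tau_field = 1.5,
                                        frame_noise = 0), "ramp")
})

test_that("quasi-spherical series keeps its baseline reduced volume near 1", {
  s <- gen_deformation_series(r_max = 1.05, frame_noise = 0)
  nu <- analyze_series(s)$nu_baseline
  expect_gt(nu, 0.95); expect_lt(nu, 1)
})

test_that("contour generator feeds the fitters their exact shapes back", {
  ce <- gen_contour(spheroid_shape(3, 2), n_points = 50, point_noise = 0)
  expect_equal(fit_ellipse(ce)$a, 3, tolerance = 1e-9)
  expect_error(gen_contour(spheroid_shape(3, 2), n_points = 4), "at least 6")
  expect_error(gen_contour(budded_shape(3, 2), n_points = 8), "at least 10")
  expect_error(gen_contour(spheroid_shape(3, 2), n_points = 50,
                           point_noise = 0.1), "seed")
})

test_that("elution generator records true areas and warns on truncated peaks", {
  tr <- gen_elution_trace(peaks = data.frame(center = 5, sigma = 0.2,
                                             amplitude = 3),
                          v_range = c(3, 7))
  expect_equal(attr(tr, "true_areas"), 3 * 0.2 * sqrt(2 * pi))
  flat <- gen_elution_trace(peaks = data.frame(center = 5, sigma = 0.2,
                                               amplitude = 0),
                            v_range = c(3, 7))
  expect_true(all(flat$absorbance_AU == 0))
  expect_warning(gen_elution_trace(peaks = data.frame(center = 3.1,
                                                      sigma = 0.5,
                                                      amplitude = 1),
                                   v_range = c(3, 7)), "truncated")
  expect_error(gen_elution_trace(noise_sd = 0.01), "seed")
})
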