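## Seeded synthetic-data generators with known ground truth, standing in for
## the microscopy and chromatography raw data: budded-shape populations with
## a prescribed true spontaneous curvature, electrodeformation time series,
## vesicle contours, and SEC elution traces.  Every stochastic generator
## requires an explicit seed; there is no implicit randomness.

## Evaluate code under a given seed without disturbing the caller's RNG
## stream.  seed = NULL runs the code as-is (only allowed for noise-free
## deterministic output).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a budded-vesicle population with known spontaneous curvature
#'
#' Samples mother-vesicle radii from a log-normal law and, for each, solves
#' the closed-neck condition for the bud radius that yields exactly the
#' prescribed local spontaneous curvature \code{m_true} at the given rigidity
#' ratio (bracketed bisection on \eqn{R_\beta \in (0, R_\alpha)}).
#' Multiplicative Gaussian measurement noise is then applied to both radii.
#' Mother radii for which no admissible bud exists (curvature too small for
#' the sampled vesicle size) are rejected and counted, not clamped.
#'
#' @param n Number of vesicles to generate (after rejection).
#' @param m_true True local spontaneous curvature, 1/um.  The default
#'   0.4 = 1/(2.5 um) is the micron scale typical of sugar-asymmetry and
#'   photoswitch-induced curvatures in GUVs.
#' @param kappa_ratio Rigidity ratio \eqn{\kappa'/\kappa} used in the neck
#'   condition.
#' @param R_alpha_median,R_alpha_sdlog Log-normal law of the mother radius,
#'   um (median) and log-sd; defaults 7.5 um and 0.25 emulate a typical GUV
#'   batch.
#' @param radius_noise Relative s.d. of the multiplicative Gaussian noise on
#'   each radius (default 0.02, i.e. 2\% measurement error).
#' @param seed Integer seed; mandatory.
#' @param max_tries Sampling attempts before giving up on rejections.
#' @return List with \code{shapes} (data frame \code{vesicle_id},
#'   \code{R_alpha_um}, \code{R_beta_um}), \code{truth} (generator
#'   parameters plus the noise-free radii), and \code{n_rejected}.
#' @examples
#' pop <- gen_budded_population(n = 10, m_true = 0.4, seed = 7)
#' neck_fit(pop$shapes, kappa_ratio = 0)
#' @export
gen_budded_population <- function(n = 30L, m_true = 0.4, kappa_ratio = 0,
                                  R_alpha_median = 7.5, R_alpha_sdlog = 0.25,
                                  radius_noise = 0.02, seed,
                                  max_tries = 100L * n) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(n >= 1L, m_true > 0, kappa_ratio >= 0, R_alpha_median > 0,
            R_alpha_sdlog >= 0, radius_noise >= 0)
  with_seed(seed, {
    Ra_clean <- numeric(0); Rb_clean <- numeric(0)
    rejected <- 0L; tries <- 0L
    while (length(Ra_clean) < n && tries < max_tries) {
      tries <- tries + 1L
      Ra <- stats::rlnorm(1, meanlog = log(R_alpha_median),
                          sdlog = R_alpha_sdlog)
      ## m(R_beta) decreases from +Inf (tiny bud) to its minimum at
      ## R_beta = R_alpha; a root exists iff m_true >= that minimum.
      m_at <- function(Rb) neck_curvature(budded_shape(Ra, Rb), kappa_ratio)$m
      if (m_at(Ra) > m_true) { rejected <- rejected + 1L; next }
      Rb <- bisect(function(Rb) m_at(Rb) - m_true,
                   1e-9 * Ra, Ra, tol = 1e-13 * Ra)
      Ra_clean <- c(Ra_clean, Ra); Rb_clean <- c(Rb_clean, Rb)
    }
    if (length(Ra_clean) < n)
      stop("could not generate ", n, " admissible shapes in ", max_tries,
           " tries (", rejected, " rejections): m_true too small for the ",
           "sampled vesicle sizes")
    if (rejected > 0)
      message(rejected, " sampled mother radii admitted no bud and were rejected")
    noise_a <- 1 + radius_noise * stats::rnorm(n)
    noise_b <- 1 + radius_noise * stats::rnorm(n)
    Ra_obs <- Ra_clean * noise_a
    Rb_obs <- Rb_clean * noise_b
    ## noise cannot demote the mother below the bud for realistic levels,
    ## but guard the invariant anyway
    swap <- Ra_obs < Rb_obs
    if (any(swap)) {
      tmp <- Ra_obs[swap]; Ra_obs[swap] <- Rb_obs[swap]; Rb_obs[swap] <- tmp
    }
    list(shapes = data.frame(vesicle_id = seq_len(n),
                             R_alpha_um = Ra_obs, R_beta_um = Rb_obs),
         truth = list(m_true = m_true, kappa_ratio = kappa_ratio,
                      seed = seed, radius_noise = radius_noise,
                      R_alpha_clean = Ra_clean, R_beta_clean = Rb_clean),
         n_rejected = rejected)
  })
}

#' Generate budded shapes exactly on a limit-shape line
#'
#' Noise-free shapes sampled along the closed-neck limit line for a given
#' rigidity ratio: for each bud ratio \code{x} the shape
#' \code{(R_alpha = scale, R_beta = scale * x)}.  Used for data-collapse
#' checks.
#'
#' @param x_grid Bud-to-mother ratios in (0, 1].
#' @param kappa_ratio Rigidity ratio.
#' @param scale Mother radius, um.
#' @return Data frame \code{R_alpha_um}, \code{R_beta_um} with the implied
#'   \code{nu} and \code{m_bar} attached as columns.
#' @export
gen_limit_line_shapes <- function(x_grid, kappa_ratio = 0, scale = 10) {
  stopifnot(all(x_grid > 0), all(x_grid <= 1), scale > 0)
  ln <- limit_shape_line(kappa_ratio, x_grid)
  data.frame(vesicle_id = seq_along(ln$x),
             R_alpha_um = scale, R_beta_um = scale * ln$x,
             nu = ln$nu, m_bar = ln$m_bar)
}

#' Generate an electrodeformation time series
#'
#' Emulates a UV-irradiation electrodeformation experiment at constant
#' vesicle volume: the AC field first elongates the vesicle, its aspect
#' ratio rising as \eqn{r(t) = 1 + (r_{max}-1)(1 - e^{-t/\tau_{field}})};
#' after UV onset the membrane area grows saturatingly towards
#' \eqn{(1 + \Delta A_{max})} times the pre-UV baseline area, the growth
#' normalised so the configured maximum is attained exactly at the final
#' frame.  Frames are prolate spheroids of the prescribed area at fixed
#' volume (via \code{\link{spheroid_from_area_volume}}), so the enclosed
#' volume is conserved to numerical precision before noise.
#'
#' @param R0 Radius of the relaxed (spherical) vesicle, um.
#' @param r_max Aspect-ratio plateau of the field-driven ramp (\code{>= 1}).
#' @param tau_field Field-deformation time constant, s.
#' @param t_uv UV onset time, s (default 7.2 s).
#' @param delta_A_max Relative area increase at full photoisomerisation
#'   (default 0.046).
#' @param tau_uv Area-growth time constant, s.
#' @param frame_dt Frame interval, s.
#' @param t_end Last frame time, s.
#' @param frame_noise Relative s.d. of the multiplicative Gaussian
#'   measurement noise on the apparent aspect ratio; each frame's semiaxes
#'   are reconstructed from the noisy aspect ratio at the true volume, so
#'   both semiaxes carry multiplicative errors but the frame volume remains
#'   exactly conserved (the vesicle volume is optically verified constant).
#' @param seed Integer seed; required when \code{frame_noise > 0}.
#' @return A \code{\link{deformation_series}} with attribute \code{truth}
#'   (the generator parameters and the noise-free baseline area).
#' @examples
#' s <- gen_deformation_series(delta_A_max = 0.046, frame_noise = 0)
#' analyze_series(s)
#' @export
gen_deformation_series <- function(R0 = 10, r_max = 1.05, tau_field = 1.5,
                                   t_uv = 7.2, delta_A_max = 0.046,
                                   tau_uv = 10, frame_dt = 0.2, t_end = 40,
                                   frame_noise = 0, seed = NULL) {
  stopifnot(R0 > 0, r_max >= 1, tau_field > 0, tau_uv > 0, frame_dt > 0,
            t_end > t_uv, delta_A_max >= 0, frame_noise >= 0)
  if (frame_noise > 0 && is.null(seed))
    stop("an explicit seed is required when frame_noise > 0")
  if (t_uv < 3 * tau_field)
    warning("UV onset at ", t_uv, " s before the field ramp (tau = ",
            tau_field, " s) is substantially complete")
  t <- seq(0, t_end, by = frame_dt)
  uv_on <- t >= t_uv
  V0 <- 4 / 3 * pi * R0^3
  a <- b <- numeric(length(t))

  shape_of_aspect <- function(r) {
    bb <- (3 * V0 / (4 * pi * r))^(1 / 3)
    c(a = r * bb, b = bb)
  }
  pre <- which(!uv_on)
  for (i in pre) {
    r <- 1 + (r_max - 1) * (1 - exp(-t[i] / tau_field))
    ab <- shape_of_aspect(r)
    a[i] <- ab[1]; b[i] <- ab[2]
  }
  ## Baseline: area at maximal pre-UV deformation (the last pre-UV frame,
  ## since the ramp is monotone).
  ib <- pre[length(pre)]
  A_base <- spheroid_area(a = a[ib], b = b[ib])
  post <- which(uv_on)
  if (length(post)) {
    g_raw <- 1 - exp(-(t[post] - t_uv) / tau_uv)
    g <- if (max(g_raw) > 0) g_raw / max(g_raw) else g_raw
    for (k in seq_along(post)) {
      A_t <- A_base * (1 + delta_A_max * g[k])
      s <- spheroid_from_area_volume(A_t, V0)
      a[post[k]] <- s$a; b[post[k]] <- s$b
    }
  }
  if (frame_noise > 0) {
    ## Shape-measurement noise at fixed volume: the apparent aspect ratio is
    ## perturbed multiplicatively and the semiaxes reconstructed at the true
    ## volume, so both a and b acquire (anti-correlated) multiplicative
    ## errors while the frame volume stays exactly conserved — matching the
    ## optical observation that the vesicle volume never changes.
    with_seed(seed, {
      r_noisy <- pmax((a / b) * (1 + frame_noise * stats::rnorm(length(a))),
                      1)
      for (i in seq_along(a)) {
        ab <- shape_of_aspect(r_noisy[i])
        a[i] <- ab[1]; b[i] <- ab[2]
      }
    })
  }
  out <- deformation_series(data.frame(t_s = t, a_um = a, b_um = b,
                                       uv_on = uv_on))
  attr(out, "truth") <- list(R0 = R0, r_max = r_max, tau_field = tau_field,
                             t_uv = t_uv, delta_A_max = delta_A_max,
                             tau_uv = tau_uv, frame_noise = frame_noise,
                             seed = seed, A_baseline = A_base, V = V0)
  out
}

#' Generate a noisy vesicle contour
#'
#' Samples points on the 2-D section outline of a prolate vesicle (an
#' ellipse) or of a two-sphere budded vesicle (two externally tangent
#' circles, points allocated to each lobe in proportion to its
#' circumference), then adds isotropic Gaussian position noise.
#'
#' @param shape A \code{\link{spheroid_shape}} (ellipse section, long axis
#'   along x) or \code{\link{budded_shape}} (mother centred at the origin,
#'   bud on the +x axis).
#' @param n_points Number of contour points (\code{>= 6} for ellipses,
#'   \code{>= 10} for budded outlines).
#' @param point_noise Isotropic Gaussian s.d. per coordinate, um.
#' @param seed Integer seed; required when \code{point_noise > 0}.
#' @param center Outline centre offset, um.
#' @param angle Rotation of the outline, radians.
#' @return A \code{\link{vesicle_contour}}.
#' @export
gen_contour <- function(shape, n_points = 100L, point_noise = 0, seed = NULL,
                        center = c(0, 0), angle = 0) {
  stopifnot(n_points >= 1L, point_noise >= 0)
  if (point_noise > 0 && is.null(seed))
    stop("an explicit seed is required when point_noise > 0")
  if (inherits(shape, "spheroid_shape")) {
    if (n_points < 6L)
      stop("need at least 6 points for an ellipse outline")
    th <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
    x <- shape$a * cos(th); y <- shape$b * sin(th)
  } else if (inherits(shape, "budded_shape")) {
    if (n_points < 10L)
      stop("need at least 10 points for a budded outline")
    R <- shape$R_alpha; r <- shape$R_beta
    n1 <- max(5L, round(n_points * R / (R + r)))
    n2 <- max(5L, n_points - n1)
    th1 <- seq(0, 2 * pi, length.out = n1 + 1L)[-(n1 + 1L)]
    th2 <- seq(0, 2 * pi, length.out = n2 + 1L)[-(n2 + 1L)]
    x <- c(R * cos(th1), (R + r) + r * cos(th2))
    y <- c(R * sin(th1), r * sin(th2))
  } else stop("shape must be a spheroid_shape or budded_shape")
  if (angle != 0) {
    xr <- x * cos(angle) - y * sin(angle)
    y <- x * sin(angle) + y * cos(angle)
    x <- xr
  }
  x <- x + center[1]; y <- y + center[2]
  if (point_noise > 0) {
    with_seed(seed, {
      x <- x + point_noise * stats::rnorm(length(x))
      y <- y + point_noise * stats::rnorm(length(y))
    })
  }
  vesicle_contour(x, y)
}

#' Default three-peak SEC profile
#'
#' Peak table emulating a vesicle + photoswitch elution profile: a small
#' membrane-incorporated peak near 5.4 mL and two free-molecule peaks near
#' 7.0 and 8.1 mL.  The incorporated amplitude is chosen so that its share
#' of the total Gaussian area equals \code{incorporated_share}.
#'
#' @param incorporated_share Fraction (not percent) of total peak area in
#'   the incorporated peak; default 0.0074.
#' @return Data frame with columns \code{center}, \code{sigma},
#'   \code{amplitude} (mL, mL, AU) and a \code{role} column.
#' @export
sec_default_peaks <- function(incorporated_share = 0.0074) {
  stopifnot(incorporated_share >= 0, incorporated_share < 1)
  ## Free-peak width 0.25 mL keeps the membrane peak at 5.4 mL
  ## baseline-resolved from the free peaks, as in measured profiles, while
  ## the 7.0 and 8.1 mL peaks still overlap in their shared tail.
  free <- data.frame(center = c(7.0, 8.1), sigma = c(0.25, 0.25),
                     amplitude = c(1.0, 0.8))
  area_free <- sum(free$amplitude * free$sigma * sqrt(2 * pi))
  sigma_inc <- 0.15
  area_inc <- incorporated_share / (1 - incorporated_share) * area_free
  inc <- data.frame(center = 5.4, sigma = sigma_inc,
                    amplitude = area_inc / (sigma_inc * sqrt(2 * pi)))
  out <- rbind(inc, free)
  out$role <- c("incorporated", "free", "free")
  out
}

#' Generate a synthetic SEC elution trace
#'
#' Sum of Gaussian peaks sampled on a uniform elution-volume grid, with the
#' true analytic area \eqn{h \sigma \sqrt{2\pi}} of every peak recorded as
#' ground truth.  Warns when a peak's +/-4 sigma support crosses the grid
#' boundary (its sampled area would then be truncated).
#'
#' @param peaks Data frame with columns \code{center}, \code{sigma},
#'   \code{amplitude}; default \code{\link{sec_default_peaks}()}.
#' @param v_range Sampled elution-volume range, mL.
#' @param step Sampling step, mL.
#' @param noise_sd Additive Gaussian absorbance noise, AU.
#' @param seed Integer seed; required when \code{noise_sd > 0}.
#' @return An \code{\link{elution_trace}} with attribute \code{true_areas}
#'   (AU*mL, one per peak).
#' @export
gen_elution_trace <- function(peaks = sec_default_peaks(),
                              v_range = c(3, 10.5), step = 0.01,
                              noise_sd = 0, seed = NULL) {
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("center", "sigma", "amplitude") %in% names(peaks)),
            all(peaks$sigma > 0), all(peaks$amplitude >= 0),
            step > 0, v_range[1] < v_range[2], noise_sd >= 0)
  if (noise_sd > 0 && is.null(seed))
    stop("an explicit seed is required when noise_sd > 0")
  if (any(peaks$center - 4 * peaks$sigma < v_range[1] |
          peaks$center + 4 * peaks$sigma > v_range[2]))
    warning("peak support (+/-4 sigma) crosses the sampled volume range; ",
            "sampled areas will be truncated")
  v <- seq(v_range[1], v_range[2], by = step)
  y <- rep(0, length(v))
  for (i in seq_len(nrow(peaks)))
    y <- y + peaks$amplitude[i] *
      exp(-(v - peaks$center[i])^2 / (2 * peaks$sigma[i]^2))
  if (noise_sd > 0)
    y <- with_seed(seed, y + noise_sd * stats::rnorm(length(y)))
  out <- elution_trace(v, y)
  attr(out, "true_areas") <- peaks$amplitude * peaks$sigma * sqrt(2 * pi)
  attr(out, "peaks") <- peaks
  out
}
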