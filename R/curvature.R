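## Neck condition for closed-neck budded vesicles, local/nonlocal
## spontaneous-curvature decomposition, and limit-shape lines in the
## (reduced volume, dimensionless curvature) plane.

## Bracketed bisection; the only root finder used in this package.
## Robustness over speed: the bracket is verified and the method cannot
## diverge.  Tolerance is absolute on x.
bisect <- function(f, lower, upper, tol = 1e-12, max_iter = 200L) {
  fl <- f(lower); fu <- f(upper)
  if (!is.finite(fl) || !is.finite(fu))
    stop("non-finite function value at bracket endpoint")
  if (fl == 0) return(lower)
  if (fu == 0) return(upper)
  if (sign(fl) == sign(fu))
    stop("root not bracketed on [", format(lower), ", ", format(upper), "]")
  for (i in seq_len(max_iter)) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    if (!is.finite(fm)) stop("non-finite function value during bisection")
    if (fm == 0 || (upper - lower) / 2 < tol) return(mid)
    if (sign(fm) == sign(fl)) { lower <- mid; fl <- fm } else upper <- mid
  }
  (lower + upper) / 2
}

## Nonlocal spontaneous curvature of the two-sphere shape.  Isolated here so
## the algebraic grouping of the neck condition lives in exactly one place:
##   m_nlo = (pi kappa_ratio) [sqrt(R_a^2+R_b^2) - R_a - R_b] / (R_a^2+R_b^2)
## The bracketed difference is negative for all positive radii, so
## m_nlo <= 0 whenever kappa_ratio >= 0 — the area-difference-elasticity
## contribution always opposes outward budding here.
nonlocal_curvature <- function(R_alpha, R_beta, kappa_ratio) {
  s2 <- R_alpha^2 + R_beta^2
  pi * kappa_ratio * (sqrt(s2) - R_alpha - R_beta) / s2
}

#' Spontaneous curvature from the closed-neck condition
#'
#' For a budded vesicle idealised as two tangent spheres (mother radius
#' \eqn{R_\alpha}, bud radius \eqn{R_\beta}) the neck stays closed when the
#' effective spontaneous curvature equals the mean of the two sphere
#' curvatures,
#' \deqn{m_{eff} = m + m_{nlo} = \tfrac12 (1/R_\alpha + 1/R_\beta),}
#' where the nonlocal contribution from area-difference elasticity is
#' \deqn{m_{nlo} = \pi \frac{\kappa'}{\kappa}
#'   \frac{\sqrt{R_\alpha^2+R_\beta^2} - R_\alpha - R_\beta}
#'        {R_\alpha^2 + R_\beta^2} \le 0.}
#' Solving for the local spontaneous curvature gives
#' \eqn{2m = 1/R_\alpha + 1/R_\beta - 2 m_{nlo}}.  The dimensionless
#' curvature is \eqn{\bar m = m R_{ve}} with
#' \eqn{R_{ve} = \sqrt{R_\alpha^2 + R_\beta^2}} for the two-sphere shape.
#'
#' @param shape A \code{\link{budded_shape}}, or missing if the radii are
#'   given directly.
#' @param kappa_ratio Ratio of nonlocal to local bending rigidity
#'   \eqn{\kappa'/\kappa}, dimensionless, \code{>= 0}.  Only the ratio enters
#'   the neck condition.
#' @param R_alpha,R_beta Radii in um, used when \code{shape} is missing.
#' @return A list of class \code{"curvature_result"} with fields
#'   \code{m} (local spontaneous curvature, 1/um), \code{m_nlo} (nonlocal,
#'   \code{<= 0}), \code{m_eff = m + m_nlo}, and \code{m_bar} (dimensionless).
#' @examples
#' neck_curvature(R_alpha = 10, R_beta = 1.5, kappa_ratio = 0)
#' @export
neck_curvature <- function(shape, kappa_ratio = 0, R_alpha, R_beta) {
  if (missing(shape) || !inherits(shape, "budded_shape"))
    shape <- budded_shape(R_alpha, R_beta)
  stopifnot(is.numeric(kappa_ratio), length(kappa_ratio) == 1L)
  if (!is.finite(kappa_ratio) || kappa_ratio < 0)
    stop("kappa_ratio must be finite and >= 0")
  Ra <- shape$R_alpha; Rb <- shape$R_beta
  m_eff <- (1 / Ra + 1 / Rb) / 2
  m_nlo <- nonlocal_curvature(Ra, Rb, kappa_ratio)
  m <- m_eff - m_nlo
  R_ve <- sqrt(Ra^2 + Rb^2)
  out <- list(m = m, m_nlo = m_nlo, m_eff = m_eff, m_bar = m * R_ve,
              kappa_ratio = kappa_ratio)
  if (!all(vapply(out, is.finite, logical(1))))
    stop("non-finite curvature result: degenerate radii")
  structure(out, class = "curvature_result")
}

#' @export
print.curvature_result <- function(x, ...) {
  cat(sprintf("Neck-condition curvature (kappa'/kappa = %g):\n", x$kappa_ratio))
  cat(sprintf("  local     m     = %.6g 1/um  ( = 1/(%.3g um) )\n",
              x$m, 1 / x$m))
  cat(sprintf("  nonlocal  m_nlo = %.6g 1/um\n", x$m_nlo))
  cat(sprintf("  effective m_eff = %.6g 1/um\n", x$m_eff))
  cat(sprintf("  dimensionless m_bar = %.6g\n", x$m_bar))
  invisible(x)
}

## Reduced volume of the two-sphere shape as a function of the bud-to-mother
## ratio x = R_beta/R_alpha: nu(x) = (1 + x^3) / (1 + x^2)^(3/2).
## Strictly decreasing on (0, 1], from 1 (vanishing bud) to 1/sqrt(2).
two_sphere_nu <- function(x) (1 + x^3) / (1 + x^2)^1.5

#' Line of limit shapes in the (nu, m_bar) plane
#'
#' Locus of closed-neck two-sphere shapes for a given rigidity ratio: for
#' each bud-to-mother ratio \code{x} in \code{(0, 1]} the reduced volume and
#' the dimensionless local spontaneous curvature at which the neck closes.
#' The line separates open-neck morphologies (below) from closed-neck buds
#' (above) in the morphology diagram.  Both coordinates are scale invariant,
#' so the internal normalisation \eqn{R_\alpha = 1} is immaterial.
#'
#' @param kappa_ratio Rigidity ratio \eqn{\kappa'/\kappa}, \code{>= 0}.
#' @param x_grid Bud-to-mother ratios \eqn{R_\beta/R_\alpha} in (0, 1];
#'   at least 2 points.
#' @return A data frame of class \code{"limit_shape_line"} with columns
#'   \code{x}, \code{nu}, \code{m_bar}, sorted by \code{nu}, plus attribute
#'   \code{kappa_ratio}.
#' @examples
#' limit_shape_line(0, x_grid = seq(0.05, 1, length.out = 50))
#' @export
limit_shape_line <- function(kappa_ratio = 0,
                             x_grid = seq(0.02, 1, length.out = 200L)) {
  stopifnot(is.numeric(x_grid))
  if (length(x_grid) < 2L) stop("x_grid needs at least 2 points")
  if (any(x_grid <= 0) || any(x_grid > 1))
    stop("x_grid values must lie in (0, 1]")
  pts <- lapply(x_grid, function(x) {
    geo <- two_sphere_geometry(R_alpha = 1, R_beta = x)
    cur <- neck_curvature(budded_shape(1, x), kappa_ratio)
    c(x = x, nu = geo$nu, m_bar = cur$m_bar)
  })
  df <- as.data.frame(do.call(rbind, pts))
  df <- df[order(df$nu), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, kappa_ratio = kappa_ratio,
            class = c("limit_shape_line", "data.frame"))
}

#' Invert the limit-shape line: bud ratio from reduced volume
#'
#' Finds the unique bud-to-mother ratio \code{x} whose two-sphere shape has
#' reduced volume \code{nu}, by bracketed bisection on \code{(1e-6, 1]}
#' (tolerance 1e-12 on \code{x}); needed to place a measured reduced volume
#' on the theoretical limit line.  Note \code{nu} depends on \code{x} only,
#' not on \code{kappa_ratio}.
#'
#' @param nu Reduced volume in \code{(1/sqrt(2), 1)}.
#' @return The bud ratio \code{x} in (0, 1].
#' @examples
#' invert_limit_line(0.95)
#' @export
invert_limit_line <- function(nu) {
  stopifnot(is.numeric(nu), length(nu) == 1L)
  if (!is.finite(nu) || nu <= 1 / sqrt(2) || nu >= 1)
    stop("nu = ", format(nu),
         " outside the attainable two-sphere range (1/sqrt(2), 1)")
  bisect(function(x) two_sphere_nu(x) - nu, 1e-6, 1, tol = 1e-12)
}

#' Classify a point of the morphology diagram against the limit line
#'
#' Compares a measured \code{(nu, m_bar)} point to the limit-shape line for
#' the given rigidity ratio.  Points above the line correspond to shapes
#' whose membrane neck has closed (budded); points below to open necks.
#'
#' @param nu Reduced volume in \code{(1/sqrt(2), 1)}.
#' @param m_bar Dimensionless spontaneous curvature.
#' @param kappa_ratio Rigidity ratio \eqn{\kappa'/\kappa}.
#' @param tol Relative tolerance for declaring the point on the line.
#' @return One of \code{"below_limit_line"}, \code{"on_limit_line"},
#'   \code{"above_limit_line"}.
#' @export
classify_morphology <- function(nu, m_bar, kappa_ratio = 0, tol = 1e-6) {
  stopifnot(is.finite(m_bar))
  x <- invert_limit_line(nu)
  line_m_bar <- neck_curvature(budded_shape(1, x), kappa_ratio)$m_bar
  if (abs(m_bar - line_m_bar) <= tol * abs(line_m_bar)) return("on_limit_line")
  if (m_bar > line_m_bar) "above_limit_line" else "below_limit_line"
}

#' Classify a trajectory in the morphology diagram
#'
#' A vesicle exposed to UV light can move through the \code{(nu, m_bar)}
#' plane by gaining area only (reduced volume drops at constant curvature),
#' by gaining spontaneous curvature only, or both.  Classification is by
#' relative change of each coordinate between the first and last point.
#'
#' @param nu Reduced-volume sequence (time ordered), or a 2-column
#'   matrix/data.frame of \code{(nu, m_bar)}.
#' @param m_bar Dimensionless-curvature sequence.
#' @param threshold Relative-change threshold below which a coordinate is
#'   deemed constant (default 1\%).
#' @return One of \code{"area_increase_only"}, \code{"curvature_only"},
#'   \code{"both"}.
#' @examples
#' pathway_trajectory(c(0.99, 0.93), c(1, 1.8))
#' @export
pathway_trajectory <- function(nu, m_bar = NULL, threshold = 0.01) {
  if (is.null(m_bar)) {
    traj <- as.matrix(nu)
    if (ncol(traj) != 2L) stop("expected a 2-column (nu, m_bar) trajectory")
    nu <- traj[, 1]; m_bar <- traj[, 2]
  }
  if (length(nu) < 2L || length(m_bar) != length(nu))
    stop("need at least 2 time-ordered (nu, m_bar) points")
  n <- length(nu)
  d_nu <- abs(nu[n] - nu[1]) / abs(nu[1])
  d_mb <- abs(m_bar[n] - m_bar[1]) / abs(m_bar[1])
  nu_moves <- d_nu > threshold
  mb_moves <- d_mb > threshold
  if (nu_moves && mb_moves) return("both")
  if (nu_moves) return("area_increase_only")
  if (mb_moves) return("curvature_only")
  warning("no coordinate changed beyond the threshold; no pathway detected")
  NA_character_
}
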