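## Closed-form geometry of prolate spheroids and two-sphere budded shapes.
## Units package-wide: lengths in micrometres (um), areas um^2, volumes um^3,
## curvatures 1/um.

#' Prolate spheroid shape
#'
#' Validating constructor for a prolate spheroid with long semiaxis \code{a}
#' along the field axis and short semiaxis \code{b}.  Inputs with \code{a < b}
#' are rejected rather than swapped, to surface data-entry errors.
#'
#' @param a Long semiaxis, um.
#' @param b Short semiaxis, um.
#' @return An object of class \code{"spheroid_shape"}: a list with fields
#'   \code{a} and \code{b}.
#' @examples
#' spheroid_shape(2, 1)
#' @export
spheroid_shape <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (!is.finite(a) || !is.finite(b) || b <= 0)
    stop("semiaxes must be finite and positive")
  if (a < b)
    stop("long semiaxis a (", a, ") smaller than short semiaxis b (", b,
         "): axes mixed up?")
  structure(list(a = a, b = b), class = "spheroid_shape")
}

#' Two-sphere budded vesicle shape
#'
#' A closed-neck budded vesicle idealised as a large spherical mother vesicle
#' of radius \code{R_alpha} connected to a spherical bud of radius
#' \code{R_beta} by a neck of zero measure.
#'
#' @param R_alpha Mother-vesicle radius, um.
#' @param R_beta Bud radius, um; must not exceed \code{R_alpha}.
#' @return An object of class \code{"budded_shape"}.
#' @examples
#' budded_shape(10, 1.5)
#' @export
budded_shape <- function(R_alpha, R_beta) {
  stopifnot(is.numeric(R_alpha), is.numeric(R_beta),
            length(R_alpha) == 1L, length(R_beta) == 1L)
  if (!is.finite(R_alpha) || !is.finite(R_beta) || R_beta <= 0)
    stop("radii must be finite and positive")
  if (R_alpha < R_beta)
    stop("mother radius R_alpha (", R_alpha,
         ") smaller than bud radius R_beta (", R_beta, ")")
  structure(list(R_alpha = R_alpha, R_beta = R_beta), class = "budded_shape")
}

#' @export
print.spheroid_shape <- function(x, ...) {
  cat(sprintf("Prolate spheroid: a = %.6g um, b = %.6g um (a/b = %.6g)\n",
              x$a, x$b, x$a / x$b))
  invisible(x)
}

#' @export
print.budded_shape <- function(x, ...) {
  cat(sprintf("Budded shape: R_alpha = %.6g um, R_beta = %.6g um\n",
              x$R_alpha, x$R_beta))
  invisible(x)
}

as_spheroid <- function(shape, a, b) {
  if (!missing(shape) && inherits(shape, "spheroid_shape")) return(shape)
  spheroid_shape(a, b)
}

#' Surface area of a prolate spheroid
#'
#' Exact closed-form surface area of the prolate spheroid of revolution with
#' semiaxes \code{a >= b}: \eqn{S = 2\pi b^2 + 2\pi a b \,\arcsin(e)/e} with
#' eccentricity \eqn{e = \sqrt{1 - b^2/a^2}}.  A series branch is used when
#' \code{a/b - 1 < 1e-8} so that the sphere limit is reached continuously,
#' without dividing by the vanishing eccentricity.
#'
#' @param shape A \code{\link{spheroid_shape}}, or missing if \code{a},
#'   \code{b} are given.
#' @param a,b Semiaxes in um, used when \code{shape} is missing.
#' @return Surface area, um^2.
#' @examples
#' spheroid_area(a = 1, b = 1)   # 4*pi
#' spheroid_area(a = 2, b = 1)
#' @export
spheroid_area <- function(shape, a, b) {
  s <- as_spheroid(shape, a, b)
  a <- s$a; b <- s$b
  e2 <- 1 - (b / a)^2
  if (a / b - 1 < 1e-8) {
    ## asin(e)/e = 1 + e^2/6 + 3 e^4/40 + ...; e^2 <= ~2e-8 here, so the
    ## truncation error is far below double precision.
    f <- 1 + e2 / 6 + 3 * e2^2 / 40
  } else {
    e <- sqrt(e2)
    f <- asin(e) / e
  }
  2 * pi * b^2 + 2 * pi * a * b * f
}

#' Volume of a prolate spheroid
#'
#' \eqn{V = (4/3)\pi a b^2}.
#'
#' @inheritParams spheroid_area
#' @return Enclosed volume, um^3.
#' @export
spheroid_volume <- function(shape, a, b) {
  s <- as_spheroid(shape, a, b)
  4 / 3 * pi * s$a * s$b^2
}

#' Reduced volume
#'
#' The reduced volume \eqn{\nu = 6\sqrt{\pi}\, V / A^{3/2}} is the ratio of
#' the vesicle volume to the volume of a sphere with the same membrane area.
#' \eqn{\nu = 1} for a sphere; \eqn{\nu < 1} signals excess area.  Values in
#' \code{(1, 1 + 1e-9]} arising from round-off are clipped to 1; larger
#' values are rejected as geometrically inconsistent.
#'
#' @param A Membrane area, um^2.
#' @param V Enclosed volume, um^3.
#' @return Reduced volume, dimensionless, in (0, 1].
#' @examples
#' reduced_volume(4 * pi, 4 * pi / 3)  # sphere: 1
#' @export
reduced_volume <- function(A, V) {
  stopifnot(is.numeric(A), is.numeric(V))
  if (any(A <= 0) || any(V <= 0)) stop("area and volume must be positive")
  nu <- 6 * sqrt(pi) * V / A^1.5
  if (any(nu > 1 + 1e-9))
    stop("reduced volume ", format(max(nu)),
         " > 1: inconsistent area/volume pair")
  pmin(nu, 1)
}

#' Vesicle size
#'
#' Radius \eqn{R_{ve} = \sqrt{A/4\pi}} of the sphere with membrane area
#' \code{A}; the length scale used to non-dimensionalise the spontaneous
#' curvature.
#'
#' @param A Membrane area, um^2.
#' @return \code{R_ve}, um.
#' @export
vesicle_size <- function(A) {
  stopifnot(is.numeric(A))
  if (any(A <= 0)) stop("area must be positive")
  sqrt(A / (4 * pi))
}

#' Geometry of a two-sphere budded shape
#'
#' Area, volume, reduced volume and vesicle size of the closed-neck two-sphere
#' shape: \eqn{A = 4\pi(R_\alpha^2 + R_\beta^2)},
#' \eqn{V = (4\pi/3)(R_\alpha^3 + R_\beta^3)}, the neck contributing zero
#' measure.  The reduced volume depends only on the ratio
#' \eqn{R_\beta/R_\alpha} (scale invariance).
#'
#' @param shape A \code{\link{budded_shape}}, or missing if the radii are
#'   given.
#' @param R_alpha,R_beta Radii in um, used when \code{shape} is missing.
#' @return A list of class \code{"vesicle_geometry"} with fields \code{A},
#'   \code{V}, \code{nu}, \code{R_ve}.
#' @examples
#' two_sphere_geometry(R_alpha = 1, R_beta = 1)  # nu = 1/sqrt(2)
#' @export
two_sphere_geometry <- function(shape, R_alpha, R_beta) {
  if (missing(shape) || !inherits(shape, "budded_shape"))
    shape <- budded_shape(R_alpha, R_beta)
  A <- 4 * pi * (shape$R_alpha^2 + shape$R_beta^2)
  V <- 4 * pi / 3 * (shape$R_alpha^3 + shape$R_beta^3)
  structure(list(A = A, V = V, nu = reduced_volume(A, V),
                 R_ve = vesicle_size(A)),
            class = "vesicle_geometry")
}

#' @export
print.vesicle_geometry <- function(x, ...) {
  cat(sprintf("Vesicle geometry: A = %.6g um^2, V = %.6g um^3, nu = %.6f, R_ve = %.6g um\n",
              x$A, x$V, x$nu, x$R_ve))
  invisible(x)
}

#' Prolate spheroid with prescribed area and volume
#'
#' Inverse map used when a vesicle of fixed volume gains area: finds the
#' unique prolate spheroid \code{(a, b)} with surface area \code{A} and
#' volume \code{V}.  The aspect ratio is bracketed and bisected on a log
#' scale, then polished by Newton steps; the round trip through
#' \code{\link{spheroid_area}} and \code{\link{spheroid_volume}} is accurate
#' to better than 1e-9 relative.
#'
#' @param A Target surface area, um^2.
#' @param V Target volume, um^3; the pair must satisfy
#'   \code{reduced_volume(A, V) <= 1}.
#' @return A \code{\link{spheroid_shape}}.
#' @examples
#' spheroid_from_area_volume(spheroid_area(a = 2, b = 1), 8 * pi / 3)
#' @export
spheroid_from_area_volume <- function(A, V) {
  stopifnot(length(A) == 1L, length(V) == 1L)
  nu <- reduced_volume(A, V)  # validates admissibility (errors if nu > 1)
  if (nu >= 1 - 1e-12) {
    R <- vesicle_size(A)
    return(spheroid_shape(R, R))
  }
  ## Parameterise by aspect ratio r = a/b >= 1 at fixed volume:
  ## b = (3V / (4 pi r))^(1/3), a = r b; area is strictly increasing in r.
  area_of <- function(r) {
    b <- (3 * V / (4 * pi * r))^(1 / 3)
    spheroid_area(a = r * b, b = b)
  }
  lo <- 0; hi <- log(2)
  while (area_of(exp(hi)) < A) {
    lo <- hi; hi <- hi * 2
    if (hi > 50) stop("no prolate spheroid with this area/volume pair")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (area_of(exp(mid)) < A) lo <- mid else hi <- mid
    if (hi - lo < 1e-14) break
  }
  r <- exp((lo + hi) / 2)
  ## Newton polish on r using a central-difference derivative.
  for (i in 1:4) {
    h <- max(1e-7 * r, 1e-10)
    d <- (area_of(r + h) - area_of(r - h)) / (2 * h)
    step <- (area_of(r) - A) / d
    r_new <- r - step
    if (!is.finite(r_new) || r_new < 1) break
    r <- r_new
    if (abs(step) < 1e-14 * r) break
  }
  b <- (3 * V / (4 * pi * r))^(1 / 3)
  spheroid_shape(r * b, b)
}
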