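## Fitting vesicle outlines: ellipse fits for electrodeformed vesicles and
## two-circle fits for budded shapes.  Contours are plain point sets in um;
## no image processing happens here.

#' Vesicle contour
#'
#' @param x,y Point coordinates, um; or \code{x} a 2-column matrix/data
#'   frame.
#' @return Data frame of class \code{"contour"} with columns \code{x},
#'   \code{y}.
#' @export
vesicle_contour <- function(x, y = NULL) {
  if (is.null(y)) {
    m <- as.matrix(x)
    if (ncol(m) != 2L) stop("expected a 2-column point set")
    x <- m[, 1]; y <- m[, 2]
  }
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite contour coordinates")
  structure(data.frame(x = as.numeric(x), y = as.numeric(y)),
            class = c("contour", "data.frame"))
}

collinear <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sv <- svd(cbind(xc, yc), nu = 0, nv = 0)$d
  sv[2] < 1e-10 * max(sv[1], 1e-300)
}

#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to a 2-D point set by the numerically stabilised direct
#' least-squares conic fit (the scatter-matrix block decomposition of the
#' classical constrained fit with \eqn{4AC - B^2 = 1}), which always returns
#' an ellipse when one exists and is exact on noise-free sampled ellipses.
#' Data are centred before fitting for conditioning.
#'
#' @param contour A \code{\link{vesicle_contour}} or 2-column point set with
#'   at least 6 non-collinear points.
#' @return List of class \code{"ellipse_fit"}: \code{center} (x, y, um),
#'   \code{a}, \code{b} (semiaxes, um, \code{a >= b}), \code{angle}
#'   (orientation of the long axis from the abscissa, radians, in
#'   \code{(-pi/2, pi/2]}), and \code{rms_residual} (root-mean-square
#'   algebraic distance per point, um, used as the budding cutoff: areas are
#'   trusted only while the residual stays below a small fraction of
#'   \code{b}).
#' @examples
#' ct <- gen_contour(spheroid_shape(3, 2), n_points = 60, point_noise = 0)
#' fit_ellipse(ct)
#' @export
fit_ellipse <- function(contour) {
  if (!inherits(contour, "contour")) contour <- vesicle_contour(contour)
  x <- contour$x; y <- contour$y
  n <- length(x)
  if (n < 6L) stop("ellipse fitting needs at least 6 points, got ", n)
  if (collinear(x, y)) stop("degenerate (collinear) contour")
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my

  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M2)
  V <- Re(eg$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2  # ellipse constraint 4AC - B^2 > 0
  ok <- which(cond > 0)
  if (!length(ok)) stop("best-fitting conic is not an ellipse")
  a1 <- V[, ok[1]]
  coefs <- c(a1, Tm %*% a1)  # A, B, C, D, E, F in centred coordinates

  A <- coefs[1]; B <- coefs[2]; C <- coefs[3]
  D <- coefs[4]; E <- coefs[5]; F <- coefs[6]
  den <- B^2 - 4 * A * C
  xc <- (2 * C * D - B * E) / den
  yc <- (2 * A * E - B * D) / den
  Fc <- A * xc^2 + B * xc * yc + C * yc^2 + D * xc + E * yc + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2)
  eq <- eigen(Q, symmetric = TRUE)
  ax2 <- -Fc / eq$values            # squared semiaxes
  if (any(ax2 <= 0)) stop("best-fitting conic is not an ellipse")
  semi <- sqrt(ax2)
  long <- which.max(semi)
  vlong <- eq$vectors[, long]
  angle <- atan2(vlong[2], vlong[1])
  if (angle <= -pi / 2) angle <- angle + pi
  if (angle > pi / 2) angle <- angle - pi
  if (angle == -pi / 2) angle <- pi / 2

  ## Geometric residual: distance from each point to the ellipse, measured
  ## radially from the centre (adequate as a goodness-of-fit gauge).
  ca <- cos(angle); sa <- sin(angle)
  xr <- (xs - xc) * ca + (ys - yc) * sa
  yr <- -(xs - xc) * sa + (ys - yc) * ca
  th <- atan2(yr / semi[min(3 - long, 2)], xr / semi[long])
  ex <- semi[long] * cos(th); ey <- semi[3 - long] * sin(th)
  rms <- sqrt(mean((xr - ex)^2 + (yr - ey)^2))

  structure(list(center = c(x = xc + mx, y = yc + my),
                 a = max(semi), b = min(semi), angle = angle,
                 rms_residual = rms),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("Ellipse: center (%.4g, %.4g), a = %.6g, b = %.6g um, angle = %.4g rad, rms = %.3g um\n",
              x$center[1], x$center[2], x$a, x$b, x$angle, x$rms_residual))
  invisible(x)
}

## Algebraic (Kasa) circle fit: linear least squares on
## x^2 + y^2 = 2 cx x + 2 cy y + c.  Exact on noise-free circles.
fit_circle <- function(x, y) {
  Z <- cbind(2 * x, 2 * y, 1)
  sol <- qr.solve(Z, x^2 + y^2)
  cx <- sol[1]; cy <- sol[2]
  R <- sqrt(sol[3] + cx^2 + cy^2)
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  list(cx = cx, cy = cy, R = R, rss = sum((r - R)^2))
}

#' Two-circle fit of a budded contour
#'
#' Extracts mother and bud radii from the outline of a budded vesicle by a
#' two-circle least-squares fit: points are split into two lobes along the
#' principal axis of the point set, a circle is fitted to each lobe, and
#' point assignment / refit is iterated to convergence.  The outline is
#' deemed bud-free — raising a classed error (\code{"vesicurv_no_bud"}) —
#' when a single circle explains it better by BIC (3 vs 6 parameters on the
#' geometric residuals), or when the two fitted circles are not separated
#' lobes (centre distance below 0.9 of the larger radius, as happens when a
#' noisy single circle is split in two and fitted piecewise).
#'
#' @param contour A \code{\link{vesicle_contour}} with at least 10 points.
#' @param max_iter Maximum assignment/refit iterations.
#' @return A \code{\link{budded_shape}} with attributes \code{centers}
#'   (2 x 2 matrix) and \code{rms_residual}.
#' @examples
#' ct <- gen_contour(budded_shape(5, 1), n_points = 80, point_noise = 0)
#' fit_budded_contour(ct)
#' @export
fit_budded_contour <- function(contour, max_iter = 50L) {
  if (!inherits(contour, "contour")) contour <- vesicle_contour(contour)
  x <- contour$x; y <- contour$y
  n <- length(x)
  if (n < 10L) stop("budded-contour fitting needs at least 10 points, got ", n)
  if (collinear(x, y)) stop("degenerate (collinear) contour")

  single <- fit_circle(x, y)

  ## Initial split: project on the principal axis, cut at the midpoint
  ## between the extreme projections (deterministic).
  xc <- x - mean(x); yc <- y - mean(y)
  v <- svd(cbind(xc, yc), nu = 0)$v[, 1]
  proj <- xc * v[1] + yc * v[2]
  assign <- proj > (max(proj) + min(proj)) / 2

  fits <- NULL
  for (it in seq_len(max_iter)) {
    if (sum(assign) < 3L || sum(!assign) < 3L) break
    f1 <- fit_circle(x[assign], y[assign])
    f2 <- fit_circle(x[!assign], y[!assign])
    d1 <- abs(sqrt((x - f1$cx)^2 + (y - f1$cy)^2) - f1$R)
    d2 <- abs(sqrt((x - f2$cx)^2 + (y - f2$cy)^2) - f2$R)
    new_assign <- d1 < d2
    fits <- list(f1 = f1, f2 = f2, d = pmin(d1, d2))
    if (all(new_assign == assign)) break
    assign <- new_assign
  }
  if (is.null(fits) || sum(assign) < 3L || sum(!assign) < 3L)
    stop(errorCondition("no bud: lobe split degenerated to a single cluster",
                        class = c("vesicurv_no_bud", "error", "condition")))

  rss2 <- sum(fits$d^2)
  bic1 <- n * log(max(single$rss, 1e-300) / n) + 3 * log(n)
  bic2 <- n * log(max(rss2, 1e-300) / n) + 6 * log(n)
  if (bic1 <= bic2)
    stop(errorCondition(
      "no bud: a single circle explains the outline better (BIC)",
      class = c("vesicurv_no_bud", "error", "condition")))

  ## Two near-concentric circles mean the split just partitioned the noise
  ## of one circle: a genuine closed-neck bud sits outside its mother, with
  ## centre separation close to R_alpha + R_beta.
  sep <- sqrt((fits$f1$cx - fits$f2$cx)^2 + (fits$f1$cy - fits$f2$cy)^2)
  if (sep < 0.9 * max(fits$f1$R, fits$f2$R))
    stop(errorCondition(
      "no bud: the two fitted circles are nearly concentric",
      class = c("vesicurv_no_bud", "error", "condition")))

  Rs <- c(fits$f1$R, fits$f2$R)
  ord <- order(Rs, decreasing = TRUE)
  centers <- rbind(c(fits$f1$cx, fits$f1$cy), c(fits$f2$cx, fits$f2$cy))[ord, ]
  out <- budded_shape(Rs[ord[1]], Rs[ord[2]])
  attr(out, "centers") <- centers
  attr(out, "rms_residual") <- sqrt(mean(fits$d^2))
  out
}
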