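## Population-level neck-condition analysis: the package's central model fit.

#' Fit the closed-neck condition to a population of budded vesicles
#'
#' Applies the neck condition to every vesicle of a measured population of
#' budded shapes, for one or more values of the rigidity ratio
#' \eqn{\kappa'/\kappa}, and summarises the inferred local spontaneous
#' curvature across the population.  This is the analysis that turns a table
#' of mother/bud radii into a point cloud in the \code{(nu, m_bar)}
#' morphology diagram together with a population estimate of \code{m}.
#'
#' Because every input shape has (by assumption) a closed neck, each shape
#' lies exactly on the limit line for the chosen \code{kappa_ratio}; the
#' spread of \code{m} across vesicles reflects the vesicle-size distribution
#' and measurement noise, not model misfit.  The summary therefore reports
#' the across-vesicle standard deviation (population spread) as the primary
#' dispersion, alongside the standard error of the mean.  Means are also
#' formatted as a reciprocal length \eqn{1/(x\ \mu m)} with the uncertainty
#' on \eqn{x} propagated to first order (\eqn{sd_x = sd_m / m^2}), the
#' convention used for micron-scale spontaneous curvatures.
#'
#' @param data A data frame with numeric columns \code{R_alpha_um} and
#'   \code{R_beta_um} (one row per vesicle), e.g. read by
#'   \code{\link{read_radius_table}}.  An optional \code{vesicle_id} column
#'   is carried through.
#' @param kappa_ratio Numeric vector of rigidity ratios to analyse;
#'   default \code{c(0, 0.5, 1, 1.5, 2)}, spanning the standard range 0--2.
#' @return An object of class \code{"neck_fit"}: a list with
#'   \describe{
#'     \item{vesicles}{per-vesicle, per-ratio data frame with columns
#'       \code{vesicle_id}, \code{kappa_ratio}, \code{R_alpha_um},
#'       \code{R_beta_um}, \code{nu}, \code{m}, \code{m_nlo}, \code{m_eff},
#'       \code{m_bar};}
#'     \item{summary}{per-ratio data frame with \code{n}, \code{mean_m},
#'       \code{sd_m}, \code{sem_m}, \code{mean_m_nlo}, and the reciprocal
#'       length \code{inv_length_um} with spread \code{inv_length_sd_um};}
#'     \item{kappa_ratio}{the ratios analysed.}
#'   }
#' @examples
#' pop <- gen_budded_population(n = 10, m_true = 0.4, seed = 1)
#' fit <- neck_fit(pop$shapes, kappa_ratio = c(0, 1))
#' summary(fit)
#' @seealso \code{\link{limit_shape_line}}, \code{\link{neck_curvature}},
#'   \code{\link{gen_budded_population}}
#' @export
neck_fit <- function(data, kappa_ratio = c(0, 0.5, 1, 1.5, 2)) {
  data <- as.data.frame(data)
  if (nrow(data) == 0L) stop("empty radius table")
  req <- c("R_alpha_um", "R_beta_um")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("radius table lacks column(s): ", paste(missing_cols, collapse = ", "))
  stopifnot(is.numeric(kappa_ratio), length(kappa_ratio) >= 1L,
            all(is.finite(kappa_ratio)), all(kappa_ratio >= 0))
  ids <- if ("vesicle_id" %in% names(data)) data$vesicle_id else seq_len(nrow(data))

  shapes <- vector("list", nrow(data))
  for (i in seq_len(nrow(data))) {
    shapes[[i]] <- tryCatch(
      budded_shape(data$R_alpha_um[i], data$R_beta_um[i]),
      error = function(e) stop("row ", i, " (vesicle ", ids[i], "): ",
                               conditionMessage(e), call. = FALSE))
  }

  rows <- list()
  for (kr in kappa_ratio) {
    for (i in seq_along(shapes)) {
      geo <- two_sphere_geometry(shapes[[i]])
      cur <- neck_curvature(shapes[[i]], kr)
      rows[[length(rows) + 1L]] <- data.frame(
        vesicle_id = ids[i], kappa_ratio = kr,
        R_alpha_um = shapes[[i]]$R_alpha, R_beta_um = shapes[[i]]$R_beta,
        nu = geo$nu, m = cur$m, m_nlo = cur$m_nlo, m_eff = cur$m_eff,
        m_bar = cur$m_bar)
    }
  }
  vesicles <- do.call(rbind, rows)
  rownames(vesicles) <- NULL

  summ <- do.call(rbind, lapply(kappa_ratio, function(kr) {
    m <- vesicles$m[vesicles$kappa_ratio == kr]
    n <- length(m)
    sd_m <- if (n >= 2) stats::sd(m) else NA_real_
    mean_m <- mean(m)
    data.frame(kappa_ratio = kr, n = n, mean_m = mean_m, sd_m = sd_m,
               sem_m = sd_m / sqrt(n),
               mean_m_nlo = mean(vesicles$m_nlo[vesicles$kappa_ratio == kr]),
               inv_length_um = 1 / mean_m,
               inv_length_sd_um = sd_m / mean_m^2)
  }))
  rownames(summ) <- NULL

  structure(list(vesicles = vesicles, summary = summ,
                 kappa_ratio = kappa_ratio, n = nrow(data),
                 call = match.call()),
            class = "neck_fit")
}

#' @export
print.neck_fit <- function(x, ...) {
  cat("Closed-neck curvature analysis\n")
  cat(sprintf("  %d vesicles, kappa'/kappa in {%s}\n\n", x$n,
              paste(format(x$kappa_ratio), collapse = ", ")))
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  kappa'/kappa = %-4g  m = %.4g +/- %.2g 1/um   ( m ~ 1/(%.2g +/- %.2g um) )\n",
                s$kappa_ratio, s$mean_m, s$sd_m, s$inv_length_um,
                s$inv_length_sd_um))
  }
  invisible(x)
}

#' Summarise a neck-condition fit
#'
#' @param object A \code{\link{neck_fit}} object.
#' @param ... Unused.
#' @return The per-ratio summary data frame (class
#'   \code{"summary.neck_fit"}) with population mean, standard deviation and
#'   standard error of the local spontaneous curvature, and its
#'   reciprocal-length representation.
#' @export
summary.neck_fit <- function(object, ...) {
  structure(object$summary, class = c("summary.neck_fit", "data.frame"))
}

#' @export
print.summary.neck_fit <- function(x, digits = 4, ...) {
  cat("Population spontaneous curvature by rigidity ratio:\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Extract mean local spontaneous curvature
#'
#' @param object A \code{\link{neck_fit}}.
#' @param ... Unused.
#' @return Named vector of population-mean \code{m} (1/um), one element per
#'   rigidity ratio.
#' @export
coef.neck_fit <- function(object, ...) {
  stats::setNames(object$summary$mean_m,
                  paste0("kappa_ratio=", format(object$summary$kappa_ratio)))
}

#' Predict curvature for new budded shapes
#'
#' Applies the fitted neck condition (same rigidity ratios) to new
#' mother/bud radii.
#'
#' @param object A \code{\link{neck_fit}}.
#' @param newdata Data frame with \code{R_alpha_um}, \code{R_beta_um}.
#' @param ... Unused.
#' @return Per-vesicle per-ratio data frame as in \code{object$vesicles}.
#' @export
predict.neck_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$vesicles)
  neck_fit(newdata, kappa_ratio = object$kappa_ratio)$vesicles
}

#' Morphology-diagram plot of a neck-condition fit
#'
#' Draws the theoretical limit-shape lines for the fitted rigidity ratios in
#' the \code{(nu, m_bar)} plane and overlays the per-vesicle points.  By
#' construction of the neck condition the points fall on their own line;
#' with measurement noise they scatter about it.
#'
#' @param x A \code{\link{neck_fit}}.
#' @param xlim Reduced-volume range shown.
#' @param ... Passed to \code{\link[graphics]{plot}}.
#' @export
plot.neck_fit <- function(x, xlim = c(1 / sqrt(2), 1), ...) {
  grid <- seq(0.02, 1, length.out = 300L)
  cols <- grDevices::hcl.colors(max(length(x$kappa_ratio), 2L), "Dark 3")
  first <- TRUE
  for (i in seq_along(x$kappa_ratio)) {
    ln <- limit_shape_line(x$kappa_ratio[i], grid)
    keep <- ln$nu >= xlim[1] & ln$nu <= xlim[2]
    if (first) {
      graphics::plot(ln$nu[keep], ln$m_bar[keep], type = "l", col = cols[i],
                     xlab = expression(nu), ylab = expression(bar(m)),
                     xlim = xlim, ...)
      first <- FALSE
    } else graphics::lines(ln$nu[keep], ln$m_bar[keep], col = cols[i])
    pts <- x$vesicles[x$vesicles$kappa_ratio == x$kappa_ratio[i], ]
    graphics::points(pts$nu, pts$m_bar, col = cols[i], pch = 19, cex = 0.7)
  }
  graphics::legend("topright", bty = "n", col = cols[seq_along(x$kappa_ratio)],
                   lty = 1, pch = 19,
                   legend = paste0("kappa'/kappa = ", format(x$kappa_ratio)))
  invisible(x)
}
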