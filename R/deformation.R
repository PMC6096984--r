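## Membrane-area extraction from electrodeformation time series.
##
## An AC field elongates a quasi-spherical vesicle into a prolate spheroid,
## pulling excess area out of thermal fluctuations; the true membrane area is
## then read off the ellipse semiaxes.  UV illumination of photoswitch-doped
## vesicles adds area, which shows up as further elongation at fixed volume.

#' Electrodeformation time series
#'
#' Validating constructor for a time series of prolate semiaxes under an AC
#' field, with a per-frame UV flag.
#'
#' @param frames Data frame with numeric columns \code{t_s} (time, s,
#'   strictly increasing), \code{a_um}, \code{b_um} (semiaxes, um, with
#'   \code{a >= b > 0}) and \code{uv_on} (0/1 or logical).
#' @param field_on_time Time the AC field was switched on, s (default: first
#'   frame time).
#' @return An object of class \code{"deformation_series"}: the validated
#'   frame table with attributes \code{field_on_time} and
#'   \code{uv_onset_time} (the first frame time with \code{uv_on}; \code{NA}
#'   if UV never switches on).
#' @export
deformation_series <- function(frames, field_on_time = NULL) {
  frames <- as.data.frame(frames)
  req <- c("t_s", "a_um", "b_um", "uv_on")
  missing_cols <- setdiff(req, names(frames))
  if (length(missing_cols))
    stop("deformation series lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(frames) < 1L) stop("empty deformation series")
  if (any(!is.finite(frames$t_s))) stop("non-finite frame times")
  if (any(diff(frames$t_s) <= 0))
    stop("frame times must be strictly increasing (first violation at frame ",
         which(diff(frames$t_s) <= 0)[1] + 1L, ")")
  bad <- which(!(frames$a_um >= frames$b_um & frames$b_um > 0))
  if (length(bad))
    stop("invalid semiaxes (need a >= b > 0) at frame ", bad[1])
  frames$uv_on <- as.logical(frames$uv_on)
  if (any(is.na(frames$uv_on))) stop("uv_on must be 0/1 or logical")
  if (is.unsorted(frames$uv_on))  # UV switches on once and stays on
    stop("uv_on flag must be non-decreasing over time")
  if (is.null(field_on_time)) field_on_time <- frames$t_s[1]
  uv_onset <- if (any(frames$uv_on)) min(frames$t_s[frames$uv_on]) else NA_real_
  if (!is.na(uv_onset) && uv_onset < field_on_time)
    stop("UV onset precedes field-on time")
  structure(frames, field_on_time = field_on_time, uv_onset_time = uv_onset,
            class = c("deformation_series", "data.frame"))
}

#' Per-frame area, volume and degree of deformation
#'
#' Computes the prolate-spheroid surface area, enclosed volume and aspect
#' ratio \code{a/b} for every frame of a deformation series.
#'
#' @param series A \code{\link{deformation_series}}.
#' @return Data frame with columns \code{t_s}, \code{A_um2}, \code{V_um3},
#'   \code{aspect}, \code{uv_on}.
#' @export
area_volume_series <- function(series) {
  stopifnot(inherits(series, "deformation_series"))
  A <- mapply(function(a, b) spheroid_area(a = a, b = b),
              series$a_um, series$b_um)
  V <- 4 / 3 * pi * series$a_um * series$b_um^2
  data.frame(t_s = series$t_s, A_um2 = A, V_um3 = V,
             aspect = series$a_um / series$b_um, uv_on = series$uv_on)
}

#' Frame of maximal deformation
#'
#' Returns the frame with the largest aspect ratio \code{a/b} within the
#' pre-UV or post-UV window; ties are broken by the earliest time.  An
#' optional rolling-median filter (window 5 frames) resists single-frame
#' outliers; it is off by default so results are a deterministic function of
#' the raw frames.
#'
#' @param series A \code{\link{deformation_series}}.
#' @param window \code{"pre_uv"} or \code{"post_uv"}.
#' @param smooth Logical; apply the rolling median before the argmax.
#' @return A one-row data frame (the selected raw frame).
#' @export
max_deformation <- function(series, window = c("pre_uv", "post_uv"),
                            smooth = FALSE) {
  stopifnot(inherits(series, "deformation_series"))
  window <- match.arg(window)
  sel <- if (window == "pre_uv") !series$uv_on else series$uv_on
  if (!any(sel)) stop("no frames in the ", window, " window")
  sub <- series[sel, , drop = FALSE]
  aspect <- sub$a_um / sub$b_um
  if (smooth && nrow(sub) >= 5L)
    aspect <- stats::runmed(aspect, k = 5L, endrule = "keep")
  idx <- which.max(aspect)  # which.max takes the first maximum: earliest time
  out <- as.data.frame(sub[idx, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Relative membrane-area increase
#'
#' \eqn{\bar{\Delta A} = (A_{UV} - A)/A}: the fractional gain in membrane
#' area upon photoisomerisation, relative to the electro-smoothed baseline
#' area \code{A}.  Negative values (shrinkage) are allowed.
#'
#' @param A_baseline Baseline area at maximal pre-UV deformation, um^2.
#' @param A_uv Area under UV, um^2.
#' @return Dimensionless relative area increase.
#' @examples
#' relative_area_increase(100, 104.6)  # 0.046
#' @export
relative_area_increase <- function(A_baseline, A_uv) {
  stopifnot(is.numeric(A_baseline), is.numeric(A_uv))
  if (any(A_baseline <= 0)) stop("baseline area must be positive")
  (A_uv - A_baseline) / A_baseline
}

#' Analyse an electrodeformation series
#'
#' Extracts the baseline area (at maximal pre-UV deformation, i.e. after the
#' field has pulled the excess area out of fluctuations — not the first
#' frame), the maximal area under UV, the relative area increase, and the
#' baseline reduced volume.
#'
#' @param series A \code{\link{deformation_series}} spanning both windows.
#' @param smooth Passed to \code{\link{max_deformation}}.
#' @return An object of class \code{"area_increase_result"}: list with
#'   \code{A_baseline}, \code{A_uv_max} (um^2), \code{delta_A_rel},
#'   \code{nu_baseline}, and the two selected frames.
#' @export
analyze_series <- function(series, smooth = FALSE) {
  stopifnot(inherits(series, "deformation_series"))
  base_frame <- max_deformation(series, "pre_uv", smooth = smooth)
  uv_frame <- max_deformation(series, "post_uv", smooth = smooth)
  A0 <- spheroid_area(a = base_frame$a_um, b = base_frame$b_um)
  V0 <- spheroid_volume(a = base_frame$a_um, b = base_frame$b_um)
  A1 <- spheroid_area(a = uv_frame$a_um, b = uv_frame$b_um)
  structure(list(A_baseline = A0, A_uv_max = A1,
                 delta_A_rel = relative_area_increase(A0, A1),
                 nu_baseline = reduced_volume(A0, V0),
                 baseline_frame = base_frame, uv_frame = uv_frame),
            class = "area_increase_result")
}

#' @export
print.area_increase_result <- function(x, ...) {
  cat(sprintf("Area increase: %.3g%% (A = %.6g -> %.6g um^2), baseline nu = %.4f\n",
              100 * x$delta_A_rel, x$A_baseline, x$A_uv_max, x$nu_baseline))
  invisible(x)
}

#' Population summary: mean and standard error
#'
#' @param values Numeric vector, \code{n >= 2}.
#' @return List of class \code{"population_summary"} with \code{n},
#'   \code{mean}, \code{sd} (n-1 denominator) and \code{sem = sd/sqrt(n)}.
#' @examples
#' summarize_population(c(1, 2, 3))
#' @export
summarize_population <- function(values) {
  stopifnot(is.numeric(values))
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 values for a population summary")
  s <- stats::sd(values)
  structure(list(n = n, mean = mean(values), sd = s, sem = s / sqrt(n)),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("n = %d: mean = %.6g, sd = %.3g, sem = %.3g\n",
              x$n, x$mean, x$sd, x$sem))
  invisible(x)
}
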