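## Quantification of photoswitch incorporation into vesicle membranes from
## size-exclusion chromatography (SEC): the membrane-inserted fraction elutes
## with the vesicles, ahead of the free molecule, and its absorbance peak
## area converts to an incorporated concentration under a proportional
## (fixed-wavelength, equal extinction) calibration.

#' SEC elution trace
#'
#' @param volume_mL Elution volumes, mL, strictly increasing.
#' @param absorbance_AU Absorbance readings, AU.
#' @return Data frame of class \code{"elution_trace"}.
#' @export
elution_trace <- function(volume_mL, absorbance_AU) {
  stopifnot(is.numeric(volume_mL), is.numeric(absorbance_AU),
            length(volume_mL) == length(absorbance_AU))
  if (any(!is.finite(volume_mL)) || any(!is.finite(absorbance_AU)))
    stop("non-finite trace values")
  if (any(diff(volume_mL) <= 0))
    stop("elution volumes must be strictly increasing")
  structure(data.frame(volume_mL = volume_mL, absorbance_AU = absorbance_AU),
            class = c("elution_trace", "data.frame"))
}

#' Integrate an elution peak
#'
#' Trapezoidal integral of the absorbance over a volume window, optionally
#' above a linear baseline connecting the window endpoints.  A negative net
#' area (possible with a baseline over a dipping trace) is allowed but
#' flagged with a warning.
#'
#' @param trace An \code{\link{elution_trace}}.
#' @param v_start,v_end Window bounds, mL, inside the trace support; at
#'   least 3 samples must fall inside.
#' @param baseline \code{"none"} or \code{"linear"}.
#' @return Peak area, AU*mL.
#' @examples
#' tr <- gen_elution_trace(peaks = data.frame(center = 7, sigma = 0.3,
#'                                            amplitude = 1))
#' integrate_peak(tr, 5.5, 8.5)
#' @export
integrate_peak <- function(trace, v_start, v_end,
                           baseline = c("none", "linear")) {
  stopifnot(inherits(trace, "elution_trace"))
  baseline <- match.arg(baseline)
  if (!(v_start < v_end)) stop("need v_start < v_end")
  v <- trace$volume_mL; y <- trace$absorbance_AU
  if (v_start < v[1] || v_end > v[length(v)])
    stop("window [", v_start, ", ", v_end, "] outside trace support [",
         v[1], ", ", v[length(v)], "]")
  inside <- v >= v_start & v <= v_end
  if (sum(inside) < 3L) stop("fewer than 3 samples inside the window")
  vi <- v[inside]; yi <- y[inside]
  if (baseline == "linear") {
    slope <- (yi[length(yi)] - yi[1]) / (vi[length(vi)] - vi[1])
    yi <- yi - (yi[1] + slope * (vi - vi[1]))
  }
  area <- sum(diff(vi) * (utils::head(yi, -1) + utils::tail(yi, -1)) / 2)
  if (area < 0) warning("negative net peak area (", format(area), " AU*mL)")
  area
}

#' Concentration of membrane-incorporated photoswitch
#'
#' Proportional-response calibration: with identical molar absorbance for
#' free and membrane-inserted molecules at the detection wavelength, peak
#' area is proportional to moles, so the incorporated concentration is the
#' total concentration scaled by the incorporated share of the total peak
#' area.
#'
#' @param area_incorporated Peak area of the membrane-incorporated species,
#'   AU*mL.
#' @param area_total Total area over all peaks (free + incorporated), AU*mL.
#' @param c_total Total photoswitch concentration in the sample, molar.
#' @return Incorporated concentration, molar.
#' @export
incorporated_concentration <- function(area_incorporated, area_total,
                                       c_total) {
  stopifnot(is.numeric(area_incorporated), is.numeric(area_total),
            is.numeric(c_total))
  if (any(area_incorporated < 0)) stop("negative incorporated area")
  if (any(area_total <= 0)) stop("total peak area must be positive")
  if (any(c_total <= 0)) stop("total concentration must be positive")
  c_total * area_incorporated / area_total
}

#' Incorporated fraction of the total photoswitch
#'
#' @param c_inc Incorporated concentration, molar; at most \code{c_total}.
#' @param c_total Total concentration, molar.
#' @return Percentage of the total present in the membrane.
#' @examples
#' incorporated_fraction(1.85e-6, 0.25e-3)  # 0.74
#' @export
incorporated_fraction <- function(c_inc, c_total) {
  stopifnot(is.numeric(c_inc), is.numeric(c_total))
  if (any(c_total <= 0)) stop("total concentration must be positive")
  if (any(c_inc < 0)) stop("negative incorporated concentration")
  if (any(c_inc > c_total)) stop("incorporated exceeds total concentration")
  100 * c_inc / c_total
}

#' Lipid molecules per incorporated photoswitch molecule
#'
#' @param c_lipid Lipid concentration, molar.
#' @param c_inc Incorporated photoswitch concentration, molar.
#' @return Dimensionless ratio (lipids per switch molecule).
#' @examples
#' lipids_per_switch(0.1e-3, 1.85e-6)  # ~54
#' @export
lipids_per_switch <- function(c_lipid, c_inc) {
  stopifnot(is.numeric(c_lipid), is.numeric(c_inc))
  if (any(c_lipid <= 0)) stop("lipid concentration must be positive")
  if (any(c_inc <= 0)) stop("incorporated concentration must be positive")
  c_lipid / c_inc
}

#' Full SEC partitioning analysis
#'
#' Integrates the membrane-incorporated peak and the free-molecule peaks and
#' derives the incorporated concentration, the incorporated fraction and the
#' lipid-to-switch ratio.
#'
#' @param trace An \code{\link{elution_trace}}.
#' @param incorporated_window Length-2 numeric, mL: window of the
#'   incorporated (vesicle-bound) peak.
#' @param free_windows List of length-2 numerics, mL: windows of the
#'   free-molecule peaks.
#' @param c_total Total photoswitch concentration, molar.
#' @param c_lipid Lipid concentration, molar.
#' @param baseline Passed to \code{\link{integrate_peak}}.
#' @return List of class \code{"partitioning_result"}: \code{c_incorporated}
#'   (molar), \code{fraction_percent}, \code{lipids_per_switch}, and the
#'   integrated areas.
#' @export
partition_analysis <- function(trace, incorporated_window, free_windows,
                               c_total, c_lipid, baseline = "none") {
  a_inc <- integrate_peak(trace, incorporated_window[1],
                          incorporated_window[2], baseline)
  a_free <- vapply(free_windows,
                   function(w) integrate_peak(trace, w[1], w[2], baseline),
                   numeric(1))
  total <- a_inc + sum(a_free)
  c_inc <- incorporated_concentration(a_inc, total, c_total)
  structure(list(c_incorporated = c_inc,
                 fraction_percent = incorporated_fraction(c_inc, c_total),
                 lipids_per_switch = lipids_per_switch(c_lipid, c_inc),
                 area_incorporated = a_inc, area_free = sum(a_free),
                 area_total = total),
            class = "partitioning_result")
}

#' @export
print.partitioning_result <- function(x, ...) {
  cat(sprintf("Incorporated: %.3g M (%.3g%% of total); one switch per %.3g lipids\n",
              x$c_incorporated, x$fraction_percent, x$lipids_per_switch))
  invisible(x)
}
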