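# Parametric chromophore absorption library.
#
# Curves are sums of Gaussian peaks plus a small baseline, unit-normalized to
# a maximum of 1.  Peak positions follow the standard visible-range optical
# absorption features of bruise chromophores: the hemoglobin Soret band
# (oxy ~415 nm, deoxy ~430 nm), the oxyhemoglobin Q-bands (540/578 nm), a
# broad deoxyhemoglobin feature near 555 nm, and the bilirubin maximum near
# 460 nm.  Melanin is modeled as a monotone-decreasing background.  These are
# deliberately parametric shapes, not tabulated extinction coefficients: the
# simulator needs controllable, dependency-free curves with the documented
# maxima, not radiometric fidelity.

# FWHM -> Gaussian sigma
.fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# peak tables: center (nm), amplitude (relative), fwhm (nm)
.chromophore_peaks <- list(
  oxyhemoglobin = data.frame(
    center = c(415, 540, 578),
    amp    = c(1.00, 0.36, 0.33),
    fwhm   = c(20, 25, 25)
  ),
  deoxyhemoglobin = data.frame(
    center = c(430, 555),
    amp    = c(1.00, 0.40),
    fwhm   = c(20, 40)
  ),
  bilirubin = data.frame(
    center = 460,
    amp    = 1.00,
    fwhm   = 25
  )
)

#' Names of the chromophores in the built-in library
#' @return Character vector of chromophore identifiers.
#' @export
chromophore_names <- function() {
  c(names(.chromophore_peaks), "melanin")
}

#' Absorption curve of a skin/bruise chromophore
#'
#' Evaluates the parametric absorption curve of one chromophore on a
#' wavelength axis.  All curves are non-negative and normalized so that the
#' maximum over the *native* 400--1000 nm support is 1; on a restricted axis
#' values are therefore in `[0, 1]`.
#'
#' @param name One of [chromophore_names()]: `"oxyhemoglobin"`,
#'   `"deoxyhemoglobin"`, `"bilirubin"`, or `"melanin"`.
#' @param axis A [make_wavelength_axis()] object.
#' @return Numeric vector of absorption values, one per band.
#' @examples
#' ax <- make_wavelength_axis()
#' mu <- chromophore_absorption("oxyhemoglobin", ax)
#' ax$centers[which.max(mu)]  # in the Soret region (405-445 nm)
#' @export
chromophore_absorption <- function(name, axis) {
  stopifnot(inherits(axis, "wavelength_axis"))
  if (!is.character(name) || length(name) != 1L || !(name %in% chromophore_names())) {
    stop(sprintf(
      "unknown chromophore '%s'; available: %s",
      paste(name, collapse = ","), paste(chromophore_names(), collapse = ", ")
    ), call. = FALSE)
  }
  lambda <- axis$centers
  if (name == "melanin") {
    # monotone decreasing power-law-like background, max 1 at 400 nm
    curve <- (lambda / 400)^-3.3
    return(curve / ((400 / 400)^-3.3))
  }
  peaks <- .chromophore_peaks[[name]]
  baseline <- 0.02
  eval_curve <- function(lam) {
    v <- rep(baseline, length(lam))
    for (i in seq_len(nrow(peaks))) {
      s <- .fwhm_to_sigma(peaks$fwhm[i])
      v <- v + peaks$amp[i] * exp(-((lam - peaks$center[i])^2) / (2 * s^2))
    }
    v
  }
  # normalize against the native support so restricted axes stay consistent
  native <- seq(400, 1000, by = 0.5)
  eval_curve(lambda) / max(eval_curve(native))
}

#' Time-course parameters for hematoma chromophore kinetics
#'
#' The concentration weights of the lesion chromophores evolve with hematoma
#' age: total hemoglobin decays exponentially from its day-0 maximum as heme
#' is degraded, bilirubin rises from zero to a mid-course peak and then
#' declines, and an overall contrast-fade factor drives every lesion weight
#' to zero as the hematoma resolves.
#'
#' @param hb_decay_days e-folding time (days) of total hemoglobin decay.
#' @param bili_peak_day Age (days) at which bilirubin concentration peaks.
#' @param bili_amp Peak bilirubin weight relative to day-0 hemoglobin.
#' @param fade_horizon_days Resolution horizon: the contrast fade factor is
#'   `exp(-(age/horizon)^4)`, ~0.5 at the horizon's 0.9 multiple and
#'   effectively zero well beyond it.
#' @param oxy_frac_day0,oxy_frac_late Fraction of total hemoglobin that is
#'   oxygenated at day 0 and in the late limit (the extravasated blood
#'   deoxygenates over time).
#' @return A list of class `time_course` with the parameters above.
#' @export
time_course_params <- function(hb_decay_days = 6,
                               bili_peak_day = 7,
                               bili_amp = 0.8,
                               fade_horizon_days = 22,
                               oxy_frac_day0 = 0.75,
                               oxy_frac_late = 0.40) {
  stopifnot(
    hb_decay_days > 0, bili_peak_day > 0, bili_amp >= 0,
    fade_horizon_days > 0,
    oxy_frac_day0 >= 0, oxy_frac_day0 <= 1,
    oxy_frac_late >= 0, oxy_frac_late <= 1
  )
  structure(
    list(
      hb_decay_days = hb_decay_days, bili_peak_day = bili_peak_day,
      bili_amp = bili_amp, fade_horizon_days = fade_horizon_days,
      oxy_frac_day0 = oxy_frac_day0, oxy_frac_late = oxy_frac_late
    ),
    class = "time_course"
  )
}

#' Chromophore concentration weights at a given hematoma age
#'
#' @param age_days Hematoma age in days (>= 0).
#' @param params A [time_course_params()] object.
#' @return Named numeric vector with non-negative weights for
#'   `oxyhemoglobin`, `deoxyhemoglobin` and `bilirubin`.  At age 0 the
#'   bilirubin weight is exactly 0 and total hemoglobin is maximal; the
#'   bilirubin weight is unimodal in age; all weights tend to zero beyond
#'   the fade horizon.
#' @examples
#' time_course_weights(0)   # fresh: hemoglobin only
#' time_course_weights(7)   # mid-course: bilirubin near its peak
#' @export
time_course_weights <- function(age_days, params = time_course_params()) {
  stopifnot(inherits(params, "time_course"))
  if (length(age_days) != 1L || !is.finite(age_days) || age_days < 0) {
    stop("`age_days` must be a single non-negative number", call. = FALSE)
  }
  fade <- exp(-(age_days / params$fade_horizon_days)^4)
  hb_total <- exp(-age_days / params$hb_decay_days) * fade
  # oxygen fraction relaxes from its fresh-blood value to the late limit
  oxy_frac <- params$oxy_frac_late +
    (params$oxy_frac_day0 - params$oxy_frac_late) * exp(-age_days / 4)
  # unimodal rise-and-fall, exactly 0 at age 0, peak bili_amp at bili_peak_day
  bili <- params$bili_amp * (age_days / params$bili_peak_day) *
    exp(1 - age_days / params$bili_peak_day) * fade
  c(
    oxyhemoglobin   = hb_total * oxy_frac,
    deoxyhemoglobin = hb_total * (1 - oxy_frac),
    bilirubin       = bili
  )
}
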