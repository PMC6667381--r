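# Signal-to-concentration quantification.
#
# Three quantification routes share this module:
#  * external-standard EPR: the sample's signal is ratioed against a sample
#    of identical volume with known spin concentration (2.0 mmol/L TEMPOL);
#  * linear calibration curves with inverse prediction, used by both the
#    Fenton-EPR and the 505 nm colorimetric H2O2 assays;
#  * first-order decay rates of TEMPOL time courses (shared fit with the
#    decay module).

#' External EPR standard
#'
#' @param intensity signal of the standard (> 0).
#' @param concentration_mM spin concentration of the standard in mmol/L;
#'   defaults to the 2.0 mmol/L TEMPOL convention.
#' @return an `external_standard` list.
#' @export
external_standard <- function(intensity, concentration_mM = 2.0) {
  check_scalar(intensity, "intensity", min = 0, strict_min = TRUE)
  check_scalar(concentration_mM, "concentration_mM", min = 0, strict_min = TRUE)
  structure(list(intensity = intensity, concentration_mM = concentration_mM),
            class = "external_standard")
}

#' Quantify a signal against an external standard
#'
#' Simple proportionality: `c = c_std * intensity / intensity_std`. The
#' external standard absorbs the unknown effective sample volume in the EPR
#' cavity, which cancels in the ratio.
#'
#' @param intensity sample signal(s), >= 0.
#' @param standard an [external_standard()].
#' @return concentration(s) in mmol/L.
#' @export
signal_to_concentration <- function(intensity, standard) {
  if (!inherits(standard, "external_standard")) {
    stop_domain("`standard` must be an external_standard")
  }
  check_numeric_vec(intensity, "intensity", min = 0)
  standard$concentration_mM * intensity / standard$intensity
}

#' Build a linear calibration curve
#'
#' Ordinary least squares of signal on concentration over a standard series.
#' The intercept is free by default because blank (0 µmol/L) standards are
#' part of the series, making it estimable; `through_origin = TRUE` forces a
#' proportional response.
#'
#' @param conc_uM standard concentrations in µmol/L (at least 3, spanning a
#'   non-zero range).
#' @param signal measured responses, same length.
#' @param through_origin force a zero intercept.
#' @return a `calibration_curve`: list with `slope` (signal per µmol/L),
#'   `intercept`, `residual_sd`, calibration `range` and `n`.
#' @export
build_calibration <- function(conc_uM, signal, through_origin = FALSE) {
  check_numeric_vec(conc_uM, "conc_uM", min = 0, min_len = 3L)
  check_numeric_vec(signal, "signal", min_len = 3L)
  if (length(conc_uM) != length(signal)) {
    stop_domain("`conc_uM` and `signal` must have the same length")
  }
  rng <- range(conc_uM)
  if (diff(rng) <= 0) {
    stop_domain("degenerate design: calibration standards must span a non-zero concentration range")
  }
  if (through_origin) {
    f <- fit_through_origin(conc_uM, signal)
    slope <- f$slope; intercept <- 0; sse <- f$sse; dfree <- length(signal) - 1L
  } else {
    f <- fit_free_line(conc_uM, signal)
    slope <- f$b; intercept <- f$a; sse <- f$sse; dfree <- length(signal) - 2L
  }
  if (slope <= 0) {
    stop_domain("calibration slope is not positive; check the standard series")
  }
  structure(list(slope = slope, intercept = intercept,
                 residual_sd = sqrt(sse / max(dfree, 1L)),
                 range = rng, n = length(signal)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> signal = %.4g + %.4g * c, residual sd %.3g, range [%g, %g] umol/L (n = %d)\n",
    x$intercept, x$slope, x$residual_sd, x$range[1], x$range[2], x$n))
  invisible(x)
}

#' Inverse prediction from a calibration curve
#'
#' Maps signals back to concentrations, `c = (signal - intercept) / slope`.
#' Predictions outside the calibration range are flagged as extrapolated;
#' negative predictions are clamped to zero with a warning, the analyte
#' being physically non-negative.
#'
#' @param curve a [calibration_curve()].
#' @param signal signal value(s).
#' @return data frame with columns `conc_uM` and `extrapolated`.
#' @export
inverse_predict <- function(curve, signal) {
  if (!inherits(curve, "calibration_curve")) {
    stop_domain("`curve` must be a calibration_curve")
  }
  check_numeric_vec(signal, "signal")
  conc <- (signal - curve$intercept) / curve$slope
  extrapolated <- conc < curve$range[1] | conc > curve$range[2]
  if (any(conc < 0)) {
    warn_rostrack("negative inverse predictions clamped to 0")
    conc[conc < 0] <- 0
  }
  data.frame(conc_uM = conc, extrapolated = extrapolated)
}

#' First-order decay rate of a signal time course
#'
#' Shared log-linear fit with the decay module, used for TEMPOL loss induced
#' by oxidative stimulation: stable (low-H2O2) series give rates at the noise
#' floor, mol/L-level H2O2 gives clearly positive rates.
#'
#' @param time_min times in minutes, strictly increasing, at least 3.
#' @param intensity signal, strictly positive.
#' @return first-order rate in min^-1 (>= 0).
#' @export
fit_timecourse_decay <- function(time_min, intensity) {
  fit_decay_rate(decay_series(time_min, intensity))$k
}
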