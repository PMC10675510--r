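## Spectroscopy: VIS absorbance spectra -> compound concentration.
##
## Raw spectra (370-750 nm) are baseline-corrected by subtracting a straight
## line fitted on the 550-750 nm window (the compound and the culture media
## only absorb below 550 nm), referenced against the corresponding blank
## medium, and the peak absorbance is mapped to concentration through a
## piecewise calibration: linear at high absorbance, power law at low
## absorbance, combined as the pointwise minimum of the two branches.

#' Construct an absorbance spectrum
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param absorbance Numeric vector of optical absorbance values
#'   (dimensionless), same length as `wavelengths`.
#' @return An object of class `spectrum`: a list with elements `wavelengths`
#'   and `absorbance`.
#' @examples
#' sp <- spectrum(seq(370, 750, by = 2), rep(0.1, 191))
#' @export
spectrum <- function(wavelengths, absorbance) {
  check_numeric(wavelengths, "wavelengths")
  if (!is.numeric(absorbance) || anyNA(absorbance))
    stop_invalid("absorbance must be numeric with no missing values")
  if (length(wavelengths) != length(absorbance))
    stop_invalid("wavelengths and absorbance must have equal length")
  if (any(diff(wavelengths) <= 0))
    stop_invalid("wavelength grid must be strictly increasing")
  structure(list(wavelengths = as.numeric(wavelengths),
                 absorbance = as.numeric(absorbance)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.0f-%.0f nm, peak A = %.4g at %.0f nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              max(x$absorbance), x$wavelengths[which.max(x$absorbance)]))
  invisible(x)
}

#' Subtract a linear baseline fitted on the long-wavelength window
#'
#' Fits an ordinary least-squares line to the absorbance on the
#' `window` (default 550-750 nm, where neither the compound nor the media
#' absorb) and subtracts it over the whole grid. The mean residual on the
#' fit window is zero by construction, and the operation is idempotent.
#'
#' @param spec A [spectrum()].
#' @param window Length-2 numeric, fit window in nm (inclusive).
#' @return A baseline-corrected [spectrum()].
#' @examples
#' wl <- seq(370, 750, by = 2)
#' flat <- baselineCorrect(spectrum(wl, 0.2 + 0.001 * wl))
#' all(abs(flat$absorbance) < 1e-12)
#' @export
baselineCorrect <- function(spec, window = c(550, 750)) {
  if (!inherits(spec, "spectrum")) spec <- do.call(spectrum, as.list(spec))
  sel <- spec$wavelengths >= window[1] & spec$wavelengths <= window[2]
  if (sum(sel) < 2L)
    stop_invalid("baseline window [", window[1], ", ", window[2],
                 "] nm contains fewer than 2 grid points")
  fit <- stats::lm.fit(cbind(1, spec$wavelengths[sel]),
                       spec$absorbance[sel])
  base <- fit$coefficients[1] + fit$coefficients[2] * spec$wavelengths
  spectrum(spec$wavelengths, spec$absorbance - base)
}

#' Reference a sample spectrum against its medium
#'
#' Both spectra are baseline-corrected and their pointwise difference is
#' returned, removing the absorbance contribution of the culture medium.
#'
#' @param sample,medium [spectrum()] objects on identical wavelength grids.
#' @inheritParams baselineCorrect
#' @return A medium-referenced, baseline-corrected [spectrum()].
#' @export
mediumReference <- function(sample, medium, window = c(550, 750)) {
  if (!identical(sample$wavelengths, medium$wavelengths))
    stop_invalid("sample and medium must share the same wavelength grid")
  s <- baselineCorrect(sample, window)
  m <- baselineCorrect(medium, window)
  spectrum(s$wavelengths, s$absorbance - m$absorbance)
}

#' Construct a piecewise absorbance-to-concentration calibration
#'
#' The concentration map is `min(linear_coeff * A, (power_coeff * A)^exponent)`:
#' linear in the Beer-Lambert regime and a power law at low absorbance where
#' scattering and instrument floor effects bend the curve. Two models ship as
#' defaults: [calDMEM()] (peak absorbance at 418 nm, coefficients 25.5, 24,
#' 1.0526) and [calHPMI()] (off-peak 450 nm, coefficients 45, 55, 1.538).
#'
#' @param wavelength Read-out wavelength in nm (418 or 450 for the defaults).
#' @param linear_coeff Linear branch slope, uM per absorbance unit.
#' @param power_coeff Power branch scale, uM per absorbance unit
#'   (pre-exponent).
#' @param exponent Power branch exponent, dimensionless, `>= 1`.
#' @return An object of class `calibration_model`.
#' @export
calibrationModel <- function(wavelength, linear_coeff, power_coeff, exponent) {
  for (nm in c("wavelength", "linear_coeff", "power_coeff", "exponent"))
    check_numeric(get(nm), nm, positive = TRUE, scalar = TRUE)
  structure(list(wavelength = wavelength, linear_coeff = linear_coeff,
                 power_coeff = power_coeff, exponent = exponent),
            class = "calibration_model")
}

#' @rdname calibrationModel
#' @export
calDMEM <- function() calibrationModel(418, 25.5, 24, 1.0526)

#' @rdname calibrationModel
#' @export
calHPMI <- function() calibrationModel(450, 45, 55, 1.538)

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> A%d -> uM: min(%.4g*A, (%.4g*A)^%.4g)\n",
    as.integer(x$wavelength), x$linear_coeff, x$power_coeff, x$exponent))
  invisible(x)
}

#' Convert absorbance to concentration
#'
#' Evaluates `min(linear_coeff * A, (power_coeff * A)^exponent)`. The min
#' rule selects the power-law branch at low absorbance and the linear branch
#' at high absorbance; both branches are non-decreasing, so the composite map
#' is non-decreasing and maps 0 to 0.
#'
#' @param A Absorbance value(s), `>= 0`. Negative medium-referenced values
#'   should be clipped to zero upstream (see [absorbanceAtWavelength()]).
#' @param cal A [calibrationModel()].
#' @return Concentration(s) in uM.
#' @examples
#' concentrationFromAbsorbance(0.1, calDMEM()) # ~2.513 uM
#' @export
concentrationFromAbsorbance <- function(A, cal) {
  check_numeric(A, "A", non_negative = TRUE)
  pmin(cal$linear_coeff * A, (cal$power_coeff * A)^cal$exponent)
}

#' Invert the calibration map
#'
#' Returns the absorbance that the calibration maps to the given
#' concentration. Because the forward map is the minimum of two increasing
#' branches, its inverse is the maximum of the branch inverses.
#'
#' @param conc Concentration(s) in uM, `>= 0`.
#' @param cal A [calibrationModel()].
#' @return Absorbance value(s).
#' @export
absorbanceFromConcentration <- function(conc, cal) {
  check_numeric(conc, "conc", non_negative = TRUE)
  pmax(conc / cal$linear_coeff, conc^(1 / cal$exponent) / cal$power_coeff)
}

#' Read off the calibration-wavelength absorbance, clipped at zero
#'
#' Linear interpolation of the spectrum at `cal$wavelength`; negative values
#' (noise floor after medium referencing) are clipped to 0.
#'
#' @param spec A [spectrum()] (normally medium-referenced).
#' @param cal A [calibrationModel()] naming the read-out wavelength.
#' @return A single non-negative absorbance.
#' @export
absorbanceAtWavelength <- function(spec, cal) {
  A <- stats::approx(spec$wavelengths, spec$absorbance,
                     xout = cal$wavelength)$y
  if (is.na(A))
    stop_invalid("spectrum does not cover the calibration wavelength ",
                 cal$wavelength, " nm")
  max(A, 0)
}

#' Fit a piecewise calibration from concentration/absorbance pairs
#'
#' Pairs with absorbance at or above `split_absorbance` are fitted with a
#' straight line through the origin (least squares); pairs below it are
#' fitted with a power law by least squares on log-log scale. The split is a
#' fitting device only: at prediction time the min rule of
#' [concentrationFromAbsorbance()] selects the branch.
#'
#' @param conc Concentrations in uM.
#' @param absorbance Matching absorbance values.
#' @param split_absorbance Absorbance separating the two fit regimes
#'   (default 0.03).
#' @param wavelength Read-out wavelength recorded in the returned model.
#' @return A [calibrationModel()].
#' @export
fitCalibration <- function(conc, absorbance, split_absorbance = 0.03,
                           wavelength = 418) {
  check_numeric(conc, "conc", non_negative = TRUE)
  check_numeric(absorbance, "absorbance", non_negative = TRUE)
  if (length(conc) != length(absorbance))
    stop_invalid("conc and absorbance must have equal length")
  hi <- absorbance >= split_absorbance
  lo <- !hi & absorbance > 0 & conc > 0
  if (sum(hi) < 2L || sum(lo) < 2L)
    stop_invalid("need at least 2 pairs on each side of split_absorbance = ",
                 split_absorbance)
  # linear branch through the origin: zero concentration gives zero
  # medium-referenced absorbance by construction
  linear_coeff <- sum(conc[hi] * absorbance[hi]) / sum(absorbance[hi]^2)
  # power branch: log c = e*log p + e*log A
  fit <- stats::lm.fit(cbind(1, log(absorbance[lo])), log(conc[lo]))
  exponent <- unname(fit$coefficients[2])
  power_coeff <- exp(unname(fit$coefficients[1]) / exponent)
  calibrationModel(wavelength, linear_coeff, power_coeff, exponent)
}
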