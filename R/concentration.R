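#' In-vitro VIF calibration table
#'
#' Monotone mapping between gadolinium concentration and measured signal
#' from an in-vitro dilution series (concentrations spanning roughly 1 to
#' 40 mM). Inversion is by monotone piecewise-linear interpolation, which is
#' shape-preserving and exactly invertible everywhere inside the table
#' range.
#'
#' @param concentrations Strictly increasing concentrations, mM.
#' @param signals Strictly monotone signals (same length).
#' @return An object of class `vif_calibration`.
#' @export
vif_calibration <- function(concentrations, signals) {
  concentrations <- as.numeric(concentrations)
  signals <- as.numeric(signals)
  if (length(concentrations) != length(signals) || length(signals) < 2L)
    stop("calibration needs >= 2 matched (concentration, signal) pairs")
  if (any(diff(concentrations) <= 0))
    stop("calibration concentrations must be strictly increasing")
  d <- diff(signals)
  if (!(all(d > 0) || all(d < 0)))
    stop("calibration signals must be strictly monotone")
  structure(list(concentrations = concentrations, signals = signals,
                 increasing = all(d > 0)),
            class = "vif_calibration")
}

#' Default in-vitro calibration
#'
#' A mildly saturating signal-vs-concentration table over 0-40 mM
#' (a 0 mM baseline anchor is prepended to the nominal 1-40 mM dilution
#' range so pre-contrast signals invert to zero without extrapolation).
#'
#' @return A `vif_calibration`.
#' @export
default_vif_calibration <- function() {
  conc <- c(0, 1, 2, 3, 4, 5, 6, 8, 10, 12, 16, 20, 25, 30, 40)
  vif_calibration(conc, 1400 * (1 - exp(-conc / 18)))
}

# forward interpolation of the calibration table (signal from concentration)
calibration_signal <- function(calibration, concentration) {
  stopifnot(inherits(calibration, "vif_calibration"))
  rng <- range(calibration$concentrations)
  if (any(concentration < rng[1] | concentration > rng[2]))
    stop("concentration outside the calibrated range")
  stats::approx(calibration$concentrations, calibration$signals,
                xout = concentration, method = "linear")$y
}

#' Signal-to-concentration conversion parameters
#'
#' @param r1 Contrast agent relaxivity, L mmol^-1 s^-1 (> 0). Default 5.0,
#'   typical for gadobutrol at 3 T.
#' @param hematocrit Haematocrit fraction in `[0, 1)` used to express a
#'   whole-blood concentration as a plasma concentration (division by
#'   `1 - hematocrit`); set to 0 to disable.
#' @param pre_contrast_frames Number of leading pre-bolus frames averaged to
#'   form the signal baseline (>= 1), or `NULL` to derive it from a schedule
#'   at the call site.
#' @return An object of class `conversion_params`.
#' @export
conversion_params <- function(r1 = 5, hematocrit = 0.45,
                              pre_contrast_frames = NULL) {
  if (r1 <= 0) stop("relaxivity r1 must be > 0")
  if (hematocrit < 0 || hematocrit >= 1) stop("hematocrit must be in [0, 1)")
  if (!is.null(pre_contrast_frames) && pre_contrast_frames < 1)
    stop("pre_contrast_frames must be >= 1")
  structure(list(r1 = r1, hematocrit = hematocrit,
                 pre_contrast_frames = pre_contrast_frames),
            class = "conversion_params")
}

# number of baseline frames: explicit in params, else frames before bolus
baseline_frames <- function(params, times_min = NULL, bolus_arrival_min = NULL) {
  if (!is.null(params$pre_contrast_frames))
    return(as.integer(params$pre_contrast_frames))
  if (is.null(times_min) || is.null(bolus_arrival_min))
    stop("pre_contrast_frames not set and no schedule information supplied")
  n <- sum(times_min < bolus_arrival_min)
  if (n < 1) stop("no pre-contrast frames before bolus arrival")
  n
}

#' Extract the vascular input function from a 4D series
#'
#' Frame-wise mean signal over a manually selected set of voxels in the
#' superior sagittal sinus. At least 20 voxels are required, matching the
#' minimum used when drawing the ROI by hand.
#'
#' @param series 4D array (x, y, z, frame).
#' @param sinus_voxels Integer matrix with one row per voxel and columns
#'   (x, y, z), 1-based.
#' @return Numeric vector of length `dim(series)[4]`.
#' @export
extract_vif <- function(series, sinus_voxels) {
  stopifnot(is.array(series), length(dim(series)) == 4L)
  sinus_voxels <- as.matrix(sinus_voxels)
  if (nrow(sinus_voxels) < 20L)
    stop("at least 20 sinus voxels are required (got ", nrow(sinus_voxels), ")")
  d <- dim(series)
  if (any(sinus_voxels < 1L) ||
      any(sweep(sinus_voxels, 2L, d[1:3], ">") ))
    stop("sinus voxel index out of image bounds")
  nt <- d[4]
  out <- numeric(nt)
  for (k in seq_len(nt)) {
    idx <- cbind(sinus_voxels, k)
    out[k] <- mean(series[idx])
  }
  out
}

#' Convert a VIF signal series to plasma concentration
#'
#' Inverts the in-vitro calibration table by monotone piecewise-linear
#' interpolation, subtracts the pre-bolus baseline concentration, and
#' divides by `1 - hematocrit` so the whole-blood concentration sampled in a
#' venous sinus is expressed as a plasma concentration. Signals outside the
#' calibrated signal range are clipped to the range ends with a warning.
#'
#' @param signal Numeric signal series.
#' @param calibration A [vif_calibration()].
#' @param params A [conversion_params()].
#' @param times_min Optional time axis (minutes); when given, a plasma
#'   `conc_curve` is returned instead of a bare vector.
#' @param bolus_arrival_min Bolus arrival (minutes), used with `times_min`
#'   to count pre-bolus baseline frames when `params$pre_contrast_frames`
#'   is `NULL`.
#' @return Plasma concentration (mM), vector or `conc_curve`.
#' @export
vif_signal_to_concentration <- function(signal, calibration,
                                        params = conversion_params(),
                                        times_min = NULL,
                                        bolus_arrival_min = NULL) {
  stopifnot(inherits(calibration, "vif_calibration"),
            inherits(params, "conversion_params"))
  rng <- range(calibration$signals)
  if (any(signal < rng[1] | signal > rng[2])) {
    warning("VIF signal outside the calibrated range; clipping to range ends")
    signal <- pmin(pmax(signal, rng[1]), rng[2])
  }
  conc <- stats::approx(calibration$signals, calibration$concentrations,
                        xout = signal, method = "linear")$y
  nb <- baseline_frames(params, times_min, bolus_arrival_min)
  conc <- conc - mean(conc[seq_len(min(nb, length(conc)))])
  conc <- conc / (1 - params$hematocrit)
  if (is.null(times_min)) conc else
    conc_curve(times_min, conc, compartment = "plasma")
}

#' Convert a tissue signal series to concentration (linear relation)
#'
#' Implements the linear tissue conversion
#' \deqn{\Delta R_1(t) = (S(t)/S_0 - 1)/T_{10}, \qquad
#'       C(t) = \Delta R_1(t)/r_1,}
#' where \eqn{S_0} is the mean of the pre-contrast frames and \eqn{T_{10}}
#' the pre-contrast relaxation time of the voxel. The concentration is zero
#' at baseline by construction.
#'
#' @param signal Numeric signal series.
#' @param T10 Pre-contrast T1 of the voxel, seconds (> 0).
#' @param params A [conversion_params()].
#' @param times_min,bolus_arrival_min As in [vif_signal_to_concentration()].
#' @return Tissue concentration (mM), vector or `conc_curve`.
#' @export
tissue_signal_to_concentration <- function(signal, T10,
                                           params = conversion_params(),
                                           times_min = NULL,
                                           bolus_arrival_min = NULL) {
  stopifnot(inherits(params, "conversion_params"))
  if (!is.finite(T10) || T10 <= 0) stop("T10 must be > 0")
  nb <- baseline_frames(params, times_min, bolus_arrival_min)
  s0 <- mean(signal[seq_len(min(nb, length(signal)))])
  if (!is.finite(s0) || s0 <= 0) stop("non-positive baseline signal")
  conc <- (signal / s0 - 1) / (T10 * params$r1)
  if (is.null(times_min)) conc else
    conc_curve(times_min, conc, compartment = "tissue")
}

#' Convert a 4D tissue signal series to concentration, voxel-wise
#'
#' Vectorised application of [tissue_signal_to_concentration()] using a
#' per-voxel T10 map.
#'
#' @param series 4D signal array (x, y, z, frame).
#' @param T10_map 3D array of pre-contrast T1, seconds.
#' @param params A [conversion_params()].
#' @param n_baseline Number of leading baseline frames.
#' @param mask Optional logical 3D array; voxels outside are `NA`.
#' @return 4D concentration array (mM).
#' @export
convert_tissue_volume <- function(series, T10_map,
                                  params = conversion_params(),
                                  n_baseline, mask = NULL) {
  stopifnot(is.array(series), length(dim(series)) == 4L)
  d <- dim(series)
  if (!identical(dim(T10_map), d[1:3]))
    stop("T10 map shape does not match the image grid")
  if (n_baseline < 1) stop("need at least one baseline frame")
  nvox <- prod(d[1:3])
  S <- matrix(series, nrow = nvox, ncol = d[4])
  s0 <- rowMeans(S[, seq_len(n_baseline), drop = FALSE])
  use <- if (is.null(mask)) rep(TRUE, nvox) else as.logical(mask)
  use <- use & is.finite(s0) & s0 > 0 & is.finite(T10_map) & T10_map > 0
  C <- matrix(NA_real_, nrow = nvox, ncol = d[4])
  if (any(use)) {
    C[use, ] <- (S[use, , drop = FALSE] / s0[use] - 1) /
      (as.vector(T10_map)[use] * params$r1)
  }
  array(C, dim = d)
}
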