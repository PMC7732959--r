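#' Parametric vascular input function model
#'
#' Closed-form plasma concentration: a gamma-variate first pass plus a
#' mono-exponential recirculation/washout tail,
#' \deqn{C_p(t) = A [ (\tau/t_p)^\alpha e^{\alpha(1 - \tau/t_p)}
#'   + w (1 - e^{-k_{on}\tau}) e^{-k_{off}\tau} ], \quad \tau = t - t_0,}
#' zero before bolus arrival. The gamma-variate term peaks at `A` exactly
#' `time_to_peak` minutes after arrival. Real studies measure their input
#' function; this parametric stand-in exists so the phantom has a known,
#' smooth, realistic C_p.
#'
#' @param t_min Times in minutes.
#' @param bolus_arrival_min Bolus arrival time t0, minutes.
#' @param peak First-pass peak plasma concentration A, mM.
#' @param time_to_peak Time from arrival to the first-pass peak, minutes.
#' @param shape Gamma-variate shape \eqn{\alpha}.
#' @param washout_fraction Recirculation plateau as a fraction of `peak`.
#' @param washout_on Recirculation build-up rate, 1/min.
#' @param washout_rate Slow washout rate, 1/min.
#' @return Plasma concentration in mM at `t_min`.
#' @export
vif_model <- function(t_min, bolus_arrival_min = 16 / 60, peak = 6,
                      time_to_peak = 0.15, shape = 2,
                      washout_fraction = 0.35, washout_on = 2,
                      washout_rate = 0.05) {
  if (peak < 0) stop("peak amplitude must be >= 0")
  tau <- t_min - bolus_arrival_min
  cp <- numeric(length(t_min))
  pos <- tau > 0
  g <- (tau[pos] / time_to_peak)^shape * exp(shape * (1 - tau[pos] / time_to_peak))
  w <- washout_fraction * (1 - exp(-washout_on * tau[pos])) *
    exp(-washout_rate * tau[pos])
  cp[pos] <- peak * (g + w)
  cp
}

#' Simulate a vascular input function on an acquisition schedule
#'
#' Evaluates [vif_model()] at the schedule's time axis. The bolus arrival is
#' taken from the schedule (seconds) and the model peaks inside the fast
#' window by construction of a valid schedule.
#'
#' @param schedule An [acquisition_schedule()].
#' @param ... Passed to [vif_model()] (all parameters except
#'   `bolus_arrival_min`).
#' @return A plasma `conc_curve`.
#' @export
simulate_vif <- function(schedule, ...) {
  stopifnot(inherits(schedule, "acq_schedule"))
  t <- make_time_axis(schedule)
  if (schedule$bolus_arrival / 60 >= max(t))
    stop("bolus arrival lies after the end of the acquisition")
  conc_curve(t, vif_model(t, bolus_arrival_min = schedule$bolus_arrival / 60, ...),
             compartment = "plasma")
}

#' Patlak forward model
#'
#' One-directional (no-reflux) kinetic model: tissue concentration is a
#' linear combination of the running plasma integral and the instantaneous
#' plasma concentration,
#' \deqn{C_t(t) = K_i \int_0^t C_p\, d\tau + v_p C_p(t),}
#' with leakage rate `Ki` (1/min) and plasma volume fraction `vp`. The
#' integral uses the same trapezoidal rule as the fitting stage, so
#' forward-generated data are recovered exactly by the estimator.
#'
#' @param vif Plasma `conc_curve`.
#' @param Ki Leakage rate, 1/min (>= 0).
#' @param vp Plasma volume fraction in `[0, 1)`.
#' @return A tissue `conc_curve`.
#' @export
patlak_forward <- function(vif, Ki, vp) {
  stopifnot(inherits(vif, "conc_curve"))
  if (!is.finite(Ki) || Ki < 0) stop("Ki must be >= 0")
  if (!is.finite(vp) || vp < 0 || vp >= 1) stop("vp must be in [0, 1)")
  icp <- cumtrapz(vif$times, vif$values)
  conc_curve(vif$times, Ki * icp + vp * vif$values, compartment = "tissue")
}

#' Signal model parameters for the simulator
#'
#' The simulator maps tissue concentration to MRI signal through the
#' longitudinal relaxation rate \eqn{R_1(t) = 1/T_{10} + r_1 C(t)}. Two
#' models are available:
#' \describe{
#'   \item{`"linear"` (default)}{\eqn{S = M_0 (1 + r_1 T_{10} C)}, the
#'     first-order expansion of the spoiled-gradient-echo signal in
#'     \eqn{\Delta R_1}. It is the exact inverse of the linear
#'     signal-to-concentration converter, so a noiseless simulate/convert/fit
#'     chain is self-consistent and recovery errors isolate estimation
#'     error.}
#'   \item{`"spgr"`}{full spoiled-gradient-echo steady state
#'     \eqn{S = M_0 \sin\alpha (1 - E_1)/(1 - \cos\alpha\, E_1)},
#'     \eqn{E_1 = e^{-TR \cdot R_1}}. Converting such data back with the
#'     linear relation carries a model-form bias of roughly
#'     \eqn{TR (1/2 + \cos\alpha/(1-\cos\alpha)) / T_{10}} (about 0.2--3%
#'     for realistic settings), which this option exists to quantify.}
#' }
#'
#' @param model `"linear"` or `"spgr"`.
#' @param r1 Contrast agent relaxivity, L mmol^-1 s^-1.
#' @param TR Repetition time, seconds (spgr only).
#' @param flip_deg Flip angle in degrees, in (0, 90) (spgr only).
#' @param M0 Equilibrium signal scale (arbitrary units).
#' @return An object of class `signal_params`.
#' @export
signal_params <- function(model = c("linear", "spgr"), r1 = 5,
                          TR = 0.0032, flip_deg = 40, M0 = 1000) {
  model <- match.arg(model)
  if (r1 <= 0) stop("relaxivity r1 must be > 0")
  if (TR <= 0) stop("TR must be > 0")
  if (flip_deg <= 0 || flip_deg >= 90) stop("flip angle must be in (0, 90) degrees")
  structure(list(model = model, r1 = r1, TR = TR, flip_deg = flip_deg, M0 = M0),
            class = "signal_params")
}

#' Convert concentration to MRI signal (simulator forward direction)
#'
#' @param C Concentration in mM (vector or tissue `conc_curve`).
#' @param T10 Pre-contrast longitudinal relaxation time, seconds (> 0).
#' @param params A [signal_params()].
#' @return Signal time series (numeric vector), with `C = 0` mapping exactly
#'   to the pre-contrast baseline.
#' @export
concentration_to_signal <- function(C, T10, params = signal_params()) {
  if (inherits(C, "conc_curve")) C <- C$values
  stopifnot(inherits(params, "signal_params"))
  if (!is.finite(T10) || T10 <= 0) stop("T10 must be > 0")
  if (params$model == "linear")
    return(params$M0 * (1 + params$r1 * T10 * C))
  a <- params$flip_deg * pi / 180
  R1 <- 1 / T10 + params$r1 * C
  E1 <- exp(-params$TR * R1)
  params$M0 * sin(a) * (1 - E1) / (1 - cos(a) * E1)
}
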