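#' Contrast concentration time curve
#'
#' Container for a time-resolved gadolinium concentration, either blood
#' plasma (the vascular input function, C_p) or brain tissue (C_t).
#'
#' @param times Acquisition times in minutes, strictly increasing.
#' @param values Concentrations in mM, same length as `times`.
#' @param compartment `"plasma"` or `"tissue"`.
#' @return An object of class `conc_curve` (a list with elements `times`,
#'   `values`, `compartment`).
#' @export
conc_curve <- function(times, values, compartment = c("plasma", "tissue")) {
  compartment <- match.arg(compartment)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have the same length")
  if (length(times) < 2L) stop("a curve needs at least 2 time points")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("times and values must be finite")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = times, values = values, compartment = compartment),
            class = "conc_curve")
}

#' @export
print.conc_curve <- function(x, ...) {
  cat(sprintf("<conc_curve %s> %d points, t = [%.3f, %.3f] min, peak %.3g mM\n",
              x$compartment, length(x$times), min(x$times), max(x$times),
              max(x$values)))
  invisible(x)
}

#' @export
plot.conc_curve <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "b", pch = 16, cex = 0.5,
       xlab = "time (min)", ylab = "concentration (mM)",
       main = paste0(x$compartment, " concentration"), ...)
}

# cumulative trapezoidal integral; first value 0, exact for piecewise-linear
cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (y[-length(y)] + y[-1]) / 2))
}

#' Running integral of a plasma curve
#'
#' Cumulative trapezoidal integral of the vascular input function,
#' \eqn{\int_0^t C_p \, d\tau}, the Patlak regressor. The first value is 0
#' and the rule is exact for piecewise-linear curves.
#'
#' @param vif A `conc_curve`.
#' @return A `conc_integral` object: list with `times` (min) and `values`
#'   (mM min).
#' @export
integrate_vif <- function(vif) {
  stopifnot(inherits(vif, "conc_curve"))
  structure(list(times = vif$times, values = cumtrapz(vif$times, vif$values)),
            class = "conc_integral")
}

#' Merge a fast and a slow concentration curve
#'
#' Concatenates the two sequences of a dual-time-resolution acquisition on a
#' single strictly increasing time axis, without any resampling. Optionally
#' removes a constant inter-sequence offset by matching the value of the
#' first slow frame to the last fast frame; this is off by default because
#' the two frames are genuinely ~30 s apart, so forcing them equal corrupts
#' an internally consistent dataset (use it only when the two series have a
#' calibration step between them).
#'
#' @param fast,slow `conc_curve` objects of the same compartment; `fast`
#'   must entirely precede `slow` in time.
#' @param offset_match Logical; shift `slow` by
#'   `fast value[last] - slow value[first]`.
#' @return A single `conc_curve`.
#' @export
merge_dual_resolution <- function(fast, slow, offset_match = FALSE) {
  stopifnot(inherits(fast, "conc_curve"), inherits(slow, "conc_curve"))
  if (fast$compartment != slow$compartment)
    stop("fast and slow curves are from different compartments")
  if (max(fast$times) >= min(slow$times))
    stop("fast and slow time ranges overlap")
  v <- slow$values
  if (isTRUE(offset_match))
    v <- v + (fast$values[length(fast$values)] - v[1])
  conc_curve(c(fast$times, slow$times), c(fast$values, v),
             compartment = fast$compartment)
}
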