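#' Fit the Patlak model to a single voxel
#'
#' Ordinary least squares on the Patlak design
#' \deqn{C_t(t) = K_i \int_0^t C_p \, d\tau + v_p C_p(t)}
#' over all frames with `t >= onset`. The running integral is accumulated
#' over the full time axis (from t = 0), only the fitted frames are
#' restricted. No non-negativity constraint is imposed: noise voxels may
#' yield negative estimates, which the downstream histogram noise
#' correction relies on.
#'
#' @param Ct Tissue `conc_curve`.
#' @param vif Plasma `conc_curve` on the same time axis.
#' @param onset Start of the fit window in minutes. The conventional choice
#'   is one fast interval after bolus arrival.
#' @return List with `Ki` (1/min), `vp`, `residual` (RMS fit residual, mM)
#'   and `n_timepoints_used`.
#' @export
fit_patlak_voxel <- function(Ct, vif, onset = 0) {
  stopifnot(inherits(Ct, "conc_curve"), inherits(vif, "conc_curve"))
  if (length(Ct$times) != length(vif$times) ||
      max(abs(Ct$times - vif$times)) > 1e-9)
    stop("tissue and plasma curves must share one time axis")
  icp <- cumtrapz(vif$times, vif$values)
  use <- vif$times >= onset
  if (sum(use) < 3L) stop("need at least 3 time points after onset")
  X <- cbind(icp[use], vif$values[use])
  if (qr(X)$rank < 2L)
    stop("singular Patlak design (degenerate vascular input function)")
  fit <- stats::.lm.fit(X, Ct$values[use])
  list(Ki = fit$coefficients[1], vp = fit$coefficients[2],
       residual = sqrt(mean(fit$residuals^2)),
       n_timepoints_used = sum(use))
}

#' Fit the Patlak model voxel-wise over a volume
#'
#' Vectorised ordinary least squares: every voxel inside the mask is fitted
#' independently with the identical design as [fit_patlak_voxel()]; voxels
#' outside the mask are set to `NA` in all maps.
#'
#' @param conc_4d 4D tissue concentration array (x, y, z, frame), mM.
#' @param vif Plasma `conc_curve` whose time axis matches the frames.
#' @param mask Logical 3D array of voxels to fit (e.g. `label_map %in% 1:3`).
#' @param onset Fit window start, minutes.
#' @return An object of class `patlak_result`: list of 3D arrays `Ki_map`,
#'   `vp_map`, `residual_map`, plus `n_timepoints_used` and `onset`.
#' @export
fit_patlak_volume <- function(conc_4d, vif, mask, onset = 0) {
  stopifnot(is.array(conc_4d), length(dim(conc_4d)) == 4L,
            inherits(vif, "conc_curve"))
  d <- dim(conc_4d)
  if (d[4] != length(vif$times))
    stop("frame count does not match the VIF time axis")
  mask <- array(as.logical(mask), dim = d[1:3])
  if (!any(mask)) stop("no voxels in mask")
  icp <- cumtrapz(vif$times, vif$values)
  use <- vif$times >= onset
  if (sum(use) < 3L) stop("need at least 3 time points after onset")
  X <- cbind(icp[use], vif$values[use])
  if (qr(X)$rank < 2L)
    stop("singular Patlak design (degenerate vascular input function)")
  Y <- matrix(conc_4d, nrow = prod(d[1:3]), ncol = d[4])[, use, drop = FALSE]
  inmask <- as.vector(mask) & apply(is.finite(Y), 1L, all)
  # closed-form normal equations, shared design across voxels
  XtX <- crossprod(X)
  B <- solve(XtX, crossprod(X, t(Y[inmask, , drop = FALSE])))   # 2 x nvox
  R <- t(Y[inmask, , drop = FALSE]) - X %*% B
  ki <- vp <- res <- rep(NA_real_, prod(d[1:3]))
  ki[inmask] <- B[1, ]
  vp[inmask] <- B[2, ]
  res[inmask] <- sqrt(colMeans(R^2))
  structure(list(Ki_map = array(ki, d[1:3]), vp_map = array(vp, d[1:3]),
                 residual_map = array(res, d[1:3]),
                 n_timepoints_used = sum(use), onset = onset),
            class = "patlak_result")
}

#' @export
print.patlak_result <- function(x, ...) {
  n <- sum(is.finite(x$Ki_map))
  cat(sprintf("<patlak_result> %d fitted voxels, %d frames (onset %.2f min)\n",
              n, x$n_timepoints_used, x$onset))
  cat(sprintf("  Ki: median %.3g 1/min; vp: median %.3g\n",
              stats::median(x$Ki_map, na.rm = TRUE),
              stats::median(x$vp_map, na.rm = TRUE)))
  invisible(x)
}

#' Default Patlak fit onset for a schedule
#'
#' Bolus arrival plus one fast scan interval, in minutes.
#'
#' @param schedule An [acquisition_schedule()].
#' @return Onset in minutes.
#' @export
default_onset <- function(schedule) {
  (schedule$bolus_arrival + schedule$fast_interval) / 60
}
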