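# shared fixtures: everything is generated in code at test time

# small phantom grid that still carries >= 20 sinus voxels
small_spec <- function(noise_sd = 0, seed = 1, preset = "desk") {
  phantom_spec(grid_shape = c(12, 12, 6), noise_sd = noise_sd, seed = seed,
               preset = preset)
}

# short schedule for fast unit tests (still dual-resolution)
short_schedule <- function() {
  acquisition_schedule(fast_interval = 3.2, fast_n = 12,
                       slow_interval = 30.5, slow_n = 10, bolus_arrival = 16)
}

# constant plasma curve c on [0, t_end] minutes
constant_vif <- function(c = 1, t_end = 10, n = 21) {
  conc_curve(seq(0, t_end, length.out = n), rep(c, n), "plasma")
}

# independent fine-grid trapezoid quadrature of a function on [0, t_end]
fine_quadrature <- function(f, t_end, n = 2e5) {
  t <- seq(0, t_end, length.out = n + 1)
  y <- f(t)
  sum(diff(t) * (y[-length(y)] + y[-1]) / 2)
}

# brute-force Patlak fit by grid search over (Ki, vp), minimising SSE
grid_search_patlak <- function(Ct, vif, onset, ki_range, vp_range, n = 201) {
  icp <- c(0, cumsum(diff(vif$times) *
                       (vif$values[-length(vif$values)] + vif$values[-1]) / 2))
  use <- vif$times >= onset
  kis <- seq(ki_range[1], ki_range[2], length.out = n)
  vps <- seq(vp_range[1], vp_range[2], length.out = n)
  best <- c(NA, NA, Inf)
  for (ki in kis) {
    # for fixed ki the best vp is 1D; still scan to stay fully brute force
    pred_ki <- ki * icp[use]
    for (vp in vps) {
      sse <- sum((Ct$values[use] - pred_ki - vp * vif$values[use])^2)
      if (sse < best[3]) best <- c(ki, vp, sse)
    }
  }
  list(Ki = best[1], vp = best[2], sse = best[3])
}
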