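test_that("dual-resolution merge concatenates and handles offsets", {
  sched <- acquisition_schedule()
  vif <- simulate_vif(sched)
  nf <- sched$fast_n
  fast <- conc_curve(vif$times[1:nf], vif$values[1:nf], "plasma")
  slow <- conc_curve(vif$times[-(1:nf)], vif$values[-(1:nf)], "plasma")

  m <- merge_dual_resolution(fast, slow)
  expect_length(m$times, 59L)
  expect_equal(m$values, vif$values)

  # constant step between sequences removed when matching is on
  shifted <- conc_curve(slow$times, slow$values + 0.1, "plasma")
  mm <- merge_dual_resolution(fast, shifted, offset_match = TRUE)
  expect_equal(mm$values[nf + 1], fast$values[nf])
  expect_equal(diff(mm$values)[-nf], diff(vif$values)[-nf])
  moff <- merge_dual_resolution(fast, shifted, offset_match = FALSE)
  expect_equal(moff$values[-(1:nf)], slow$values + 0.1)

  expect_error(merge_dual_resolution(fast, fast), "overlap")
})

test_that("integrate_vif is exact for constants and ramps", {
  const <- integrate_vif(constant_vif(c = 1, t_end = 10))
  expect_equal(const$values[length(const$values)], 10)
  t <- seq(0, 5, by = 0.25)
  ramp <- integrate_vif(conc_curve(t, t, "plasma"))
  expect_equal(ramp$values, t^2 / 2)   # trapezoid exact on linear curves
})

test_that("voxel fits recover forward-model parameters to machine precision", {
  sched <- acquisition_schedule()
  vif <- simulate_vif(sched)
  onset <- default_onset(sched)
  set.seed(1)
  for (i in 1:8) {
    ki <- runif(1, 1e-4, 5e-3); vp <- runif(1, 0.001, 0.05)
    fit <- fit_patlak_voxel(patlak_forward(vif, ki, vp), vif, onset)
    expect_equal(fit$Ki, ki, tolerance = 1e-10)
    expect_equal(fit$vp, vp, tolerance = 1e-10)
    expect_lt(fit$residual, 1e-12)
  }
  # zero tissue curve -> zero parameters
  z <- conc_curve(vif$times, rep(0, 59), "tissue")
  fz <- fit_patlak_voxel(z, vif, onset)
  expect_equal(c(fz$Ki, fz$vp), c(0, 0))
  # degenerate VIF
  zero_vif <- conc_curve(vif$times, rep(0, 59), "plasma")
  expect_error(fit_patlak_voxel(z, zero_vif, onset), "singular")
})

test_that("OLS agrees with brute-force grid search on random fixtures", {
  sched <- short_schedule()
  vif <- simulate_vif(sched)
  onset <- default_onset(sched)
  set.seed(42)
  for (i in 1:5) {
    ki <- runif(1, 5e-4, 2e-3); vp <- runif(1, 0.005, 0.03)
    ct <- patlak_forward(vif, ki, vp)
    ct$values <- ct$values + rnorm(length(ct$values), sd = 2e-3)
    fit <- fit_patlak_voxel(ct, vif, onset)
    gs <- grid_search_patlak(ct, vif, onset,
                             ki_range = fit$Ki + c(-1, 1) * 5e-4,
                             vp_range = fit$vp + c(-1, 1) * 5e-3, n = 201)
    expect_equal(gs$Ki, fit$Ki, tolerance = 0.01)
    expect_equal(gs$vp, fit$vp, tolerance = 0.05)
  }
})

test_that("Ki estimates are scale-equivariant and unbiased under noise", {
  sched <- short_schedule()
  vif <- simulate_vif(sched)
  onset <- default_onset(sched)
  ct <- patlak_forward(vif, 1e-3, 0.02)
  f1 <- fit_patlak_voxel(ct, vif, onset)
  vif2 <- conc_curve(vif$times, 3 * vif$values, "plasma")
  ct2 <- conc_curve(ct$times, 3 * ct$values, "tissue")
  f2 <- fit_patlak_voxel(ct2, vif2, onset)
  expect_equal(f2$Ki, f1$Ki, tolerance = 1e-12)
  expect_equal(f2$vp, f1$vp, tolerance = 1e-12)

  # 1000 zero-mean-noise realisations of one voxel: |bias| < 2 SE
  set.seed(9)
  icp <- integrate_vif(vif)$values
  use <- vif$times >= onset
  X <- cbind(icp[use], vif$values[use])
  H <- solve(crossprod(X), t(X))
  kis <- vapply(1:1000, function(i) {
    y <- ct$values[use] + rnorm(sum(use), sd = 5e-3)
    (H %*% y)[1]
  }, numeric(1))
  expect_lt(abs(mean(kis) - 1e-3), 2 * sd(kis) / sqrt(1000))
})

test_that("volume fits equal independent voxel fits and honour the mask", {
  spec <- small_spec(noise_sd = 0)
  sched <- acquisition_schedule()
  ds <- generate_phantom_dataset(spec, sched)
  vif <- ds$vif
  onset <- default_onset(sched)
  mask <- array(ds$label_map %in% 1:3, dim = dim(ds$label_map))
  nvox <- prod(dim(mask))
  conc4 <- array(NA_real_, dim = c(dim(mask), length(vif$times)))
  for (k in seq_along(vif$times)) {
    conc4[, , , k] <- ds$true_Ki * integrate_vif(vif)$values[k] +
      ds$true_vp * vif$values[k]
  }
  pr <- fit_patlak_volume(conc4, vif, mask, onset)
  idx <- which(mask, arr.ind = TRUE)
  for (i in c(1, 10, 50)) {
    v <- idx[i, ]
    single <- fit_patlak_voxel(
      conc_curve(vif$times, conc4[v[1], v[2], v[3], ], "tissue"), vif, onset)
    expect_equal(pr$Ki_map[v[1], v[2], v[3]], single$Ki, tolerance = 1e-12)
    expect_equal(pr$vp_map[v[1], v[2], v[3]], single$vp, tolerance = 1e-12)
  }
  out_vox <- which(!mask, arr.ind = TRUE)[1, ]
  expect_true(is.na(pr$Ki_map[out_vox[1], out_vox[2], out_vox[3]]))
  expect_error(fit_patlak_volume(conc4, vif, array(FALSE, dim(mask)), onset),
               "mask")
})

test_that("noisy volume fits recover the ROI-mean Ki within 10%", {
  # noise scaled for per-voxel Ki SNR ~ 2; the WM ROI mean then averages
  # ~550 voxels, so its Monte-Carlo error is well under 10%
  spec <- phantom_spec(grid_shape = c(16, 16, 8), noise_sd = 25, seed = 31)
  sched <- acquisition_schedule()
  ds <- generate_phantom_dataset(spec, sched)
  series <- array(c(ds$fast, ds$slow),
                  dim = c(dim(ds$t1_map), length(ds$times_min)))
  bolus_min <- sched$bolus_arrival / 60
  vif <- suppressWarnings(vif_signal_to_concentration(
    extract_vif(series, sinus_voxel_indices(ds$label_map)),
    default_vif_calibration(), conversion_params(),
    times_min = ds$times_min, bolus_arrival_min = bolus_min))
  mask <- array(ds$label_map == 1L, dim = dim(ds$label_map))
  conc <- convert_tissue_volume(series, ds$t1_map, conversion_params(),
                                n_baseline = sum(ds$times_min < bolus_min),
                                mask = mask)
  pr <- fit_patlak_volume(conc, vif, mask, onset = default_onset(sched))
  expect_equal(mean(pr$Ki_map[mask]), 1.1e-3, tolerance = 0.10)
})
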