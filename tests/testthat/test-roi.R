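make_map <- function(values, code = 1L) {
  n <- length(values)
  d <- c(n, 1, 1)
  list(map = array(values, d), labels = array(rep(code, n), d))
}

test_that("histograms count every in-region voxel exactly once", {
  f <- make_map(rep(0.5, 100))
  h <- build_histogram(f$map, f$labels, "white_matter")
  expect_equal(sum(h$counts), 100)
  expect_equal(sum(h$counts > 0), 1L)
  occupied <- which(h$counts > 0)
  expect_true(h$bin_edges[occupied] < 0.5 && 0.5 <= h$bin_edges[occupied + 1])
  expect_equal(h$bin_values[occupied], 0.5)

  # counts partition by region: wm + gm(+hc) sums to all labelled voxels
  set.seed(3)
  vals <- rnorm(300)
  labels <- array(sample(c(1L, 2L, 3L), 300, TRUE), c(300, 1, 1))
  map <- array(vals, c(300, 1, 1))
  h_wm <- build_histogram(map, labels, "white_matter", bins = 12)
  h_gm <- build_histogram(map, labels, "grey_matter", bins = 12)
  expect_equal(sum(h_wm$counts) + sum(h_gm$counts), 300)

  # direct-tally oracle on uniform values
  set.seed(7)
  u <- runif(500)
  fu <- make_map(u)
  hu <- build_histogram(fu$map, fu$labels, "white_matter", bins = 10)
  tally <- vapply(seq_along(hu$counts), function(j)
    sum(u > hu$bin_edges[j] & u <= hu$bin_edges[j + 1]), numeric(1))
  expect_equal(hu$counts, tally)

  expect_error(build_histogram(f$map, array(0L, dim(f$map)), "white_matter"),
               "empty region")
  expect_error(build_histogram(f$map, f$labels, "white_matter", bins = 1),
               "bins")
})

test_that("mirrored-tail correction nulls symmetric noise and keeps signal", {
  # exactly symmetric histogram about 0 -> mean 0, noise fraction 1
  sym <- make_map(c(seq(-1, -0.1, by = 0.1), seq(0.1, 1, by = 0.1)))
  hs <- build_histogram(sym$map, sym$labels, "white_matter", bins = 20)
  cs <- noise_corrected_mean(hs)
  expect_equal(cs$corrected_mean, 0)
  expect_equal(cs$noise_fraction, 1)

  # all mass in one positive bin at k -> mean k, noise fraction 0
  pos <- make_map(rep(3.7, 50))
  cp <- noise_corrected_mean(build_histogram(pos$map, pos$labels,
                                             "white_matter"))
  expect_equal(cp$corrected_mean, 3.7)
  expect_equal(cp$noise_fraction, 0)

  # known mixture: 80% N(0,1) noise + 20% point mass at +4
  set.seed(123)
  n <- 1e5
  vals <- c(rnorm(0.8 * n), rep(4, 0.2 * n))
  mx <- make_map(vals)
  cm <- noise_corrected_mean(build_histogram(mx$map, mx$labels,
                                             "white_matter"))
  expect_equal(cm$corrected_mean, 4, tolerance = 0.05)
  expect_equal(cm$noise_fraction, 0.8, tolerance = 0.05)
})

test_that("correction removes mass monotonically and never invents it", {
  set.seed(11)
  vals <- c(rnorm(2000), rep(2, 300))
  f <- make_map(vals)
  h <- build_histogram(f$map, f$labels, "white_matter", bins = 40)
  cc <- noise_corrected_mean(h)
  expect_true(all(cc$surviving_counts <= h$counts + 1e-12))
  expect_gte(cc$noise_fraction, 0)
  expect_lte(cc$noise_fraction, 1)

  # adding positive-only mass never decreases the corrected mean
  f2 <- make_map(c(vals, rep(5, 200)))
  h2 <- build_histogram(f2$map, f2$labels, "white_matter", bins = 40)
  expect_gte(noise_corrected_mean(h2)$corrected_mean, cc$corrected_mean)
})

test_that("ROI summaries handle delta, pure-noise and missing regions", {
  d <- c(10, 10, 6)
  labels <- array(0L, d)
  labels[2:5, 2:9, ] <- 1L
  labels[6:9, 2:6, ] <- 2L
  labels[7:8, 7:8, 2:4] <- 3L

  # noiseless: WM delta at 1e-3 reproduced exactly
  ki <- array(NA_real_, d)
  ki[labels == 1L] <- 1e-3
  ki[labels %in% c(2L, 3L)] <- 2e-3
  pr <- structure(list(Ki_map = ki, vp_map = ki, residual_map = ki,
                       n_timepoints_used = 10L, onset = 0),
                  class = "patlak_result")
  s <- summarize_roi(pr, labels)
  expect_equal(s$mean_Ki_corrected[s$region == "white_matter"], 1e-3)
  expect_equal(s$noise_fraction, rep(0, 3))

  # pure symmetric noise: the mirrored subtraction leaves only the random
  # positive excess, so the corrected mean has an O(sigma) floor at finite
  # n (it is "zero" only relative to a genuine leakage signal); most of
  # the histogram mass must be flagged as noise
  set.seed(5)
  kin <- array(NA_real_, d)
  kin[labels > 0L] <- rnorm(sum(labels > 0L), 0, 1e-3)
  prn <- structure(list(Ki_map = kin, vp_map = kin, residual_map = kin,
                        n_timepoints_used = 10L, onset = 0),
                   class = "patlak_result")
  sn <- summarize_roi(prn, labels)
  expect_true(all(abs(sn$mean_Ki_corrected) < 3e-3))
  expect_true(all(sn$noise_fraction > 0.3))

  # at ROI sizes where the asymptotics bite (~1e4 voxels), pure noise is
  # almost fully flagged and the corrected mean stays below ~1.5 sigma,
  # while a genuine signal of 4 sigma survives essentially unattenuated
  big <- array(1L, c(30, 30, 12))
  set.seed(6)
  noise_map <- array(rnorm(length(big), 0, 1e-3), dim(big))
  hb <- build_histogram(noise_map, big, "white_matter")
  cb <- noise_corrected_mean(hb)
  expect_lt(abs(cb$corrected_mean), 1.6e-3)
  expect_gt(cb$noise_fraction, 0.9)
  sig_map <- noise_map + 4e-3
  csig <- noise_corrected_mean(build_histogram(sig_map, big, "white_matter"))
  expect_equal(csig$corrected_mean, 4e-3, tolerance = 0.02)

  labels2 <- labels
  labels2[labels2 == 3L] <- 2L
  expect_error(summarize_roi(pr, labels2), "hippocampus")
})
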