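#' Build a per-region histogram of a voxel map
#'
#' Histogram of all in-region, non-missing voxel values. Bin edges are
#' integer multiples of the bin width, so zero is always an edge and every
#' negative bin has an exact positive mirror bin — the layout the mirrored
#' noise correction requires. Voxels exactly at zero are split evenly
#' between the bins on either side. Each bin also records the mean of the
#' values it holds, so summaries are not limited to bin-centre resolution.
#'
#' @param map 3D numeric array (e.g. a Ki map; `NA` = unfitted).
#' @param labels 3D integer label array ([tissue_labels()] codes).
#' @param region `"white_matter"`, `"grey_matter"` (cortical + deep grey +
#'   hippocampus) or `"hippocampus"`.
#' @param bins Number of bins, or `NULL` for a Freedman-Diaconis width.
#' @return An object of class `roi_histogram`: `region`, `bin_edges`,
#'   `counts` (possibly fractional because of the zero split),
#'   `bin_values` (per-bin mean value), `n_voxels`.
#' @export
build_histogram <- function(map, labels, region, bins = NULL) {
  stopifnot(identical(dim(map), dim(labels)))
  if (!is.null(bins) && bins < 2) stop("bins must be >= 2")
  sel <- labels %in% region_codes(region) & is.finite(map)
  v <- map[sel]
  if (length(v) == 0L) stop("empty region: ", region)
  n <- length(v)
  rng <- range(v)
  h <- if (!is.null(bins)) {
    span <- max(diff(rng), abs(rng[1]), 1e-12)
    span / bins
  } else {
    iqr <- stats::IQR(v)
    w <- if (iqr > 0) 2 * iqr * n^(-1 / 3) else diff(rng) / (ceiling(log2(n)) + 1)
    if (w <= 0) max(abs(v[1]), 1) * 1e-3 else w
  }
  # bin by |value|, signed: k = ceiling(|v|/h) puts v in ((k-1)h, kh] for
  # v > 0 and in [-kh, -(k-1)h) for v < 0, so x and -x always land in exact
  # mirror bins (a plain right-closed rule would not, and the mirrored
  # noise subtraction depends on this symmetry)
  k_of <- function(x) pmax(1L, ceiling(abs(x) / h - 1e-9))
  lo <- if (rng[1] < 0) -k_of(rng[1]) else 0L
  hi <- if (rng[2] > 0) k_of(rng[2]) else 0L
  if (hi == lo) hi <- lo + 1L
  edges <- (lo:hi) * h
  nb <- length(edges) - 1L
  zero <- v == 0
  vv <- v[!zero]
  idx <- ifelse(vv > 0, k_of(vv) - lo, 1L - k_of(vv) - lo)
  idx[idx < 1L] <- 1L
  idx[idx > nb] <- nb
  counts <- as.numeric(tabulate(idx, nbins = nb))
  sums <- numeric(nb)
  if (any(!zero)) {
    s <- tapply(v[!zero], factor(idx, levels = seq_len(nb)), sum)
    sums <- ifelse(is.na(s), 0, as.numeric(s))
  }
  if (any(zero)) {
    jz <- which(abs(edges) < h / 2)[1] - 1L  # bin ending at 0
    nz <- sum(zero)
    below <- jz >= 1L
    above <- jz + 1L <= nb
    if (below && above) {
      counts[jz] <- counts[jz] + nz / 2
      counts[jz + 1L] <- counts[jz + 1L] + nz / 2
    } else if (below) {
      counts[jz] <- counts[jz] + nz
    } else {
      counts[jz + 1L] <- counts[jz + 1L] + nz
    }
  }
  bin_values <- ifelse(counts > 0, sums / counts, (edges[-1] + edges[-nb - 1L]) / 2)
  structure(list(region = region, bin_edges = edges, counts = counts,
                 bin_values = bin_values, n_voxels = n),
            class = "roi_histogram")
}

#' Mirrored-negative-tail noise correction of a leakage histogram
#'
#' Unconstrained voxel-wise Patlak fits scatter noise-only voxels
#' symmetrically around zero. The noise component of a region histogram is
#' therefore estimated by reflecting the negative-value mass about zero and
#' subtracting it bin-wise from the positive bins (floored at zero). The
#' corrected mean is the mean of the surviving positive mass (0 if nothing
#' survives), and the noise fraction is the share of the histogram mass
#' attributed to noise (negative mass plus the matched positive mass).
#'
#' @param hist A [build_histogram()] result.
#' @return List with `corrected_mean`, `noise_fraction`,
#'   `surviving_counts` (full-length vector, zero outside positive bins).
#' @export
noise_corrected_mean <- function(hist) {
  stopifnot(inherits(hist, "roi_histogram"))
  edges <- hist$bin_edges
  nb <- length(edges) - 1L
  if (nb < 1L) stop("histogram has no bins")
  centers <- (edges[-1] + edges[-nb - 1L]) / 2
  h <- edges[2] - edges[1]
  neg <- which(centers < 0)
  pos <- which(centers > 0)
  reflected <- numeric(nb)
  for (j in neg) {
    k <- which(abs(centers + centers[j]) < h / 2)  # mirror bin
    if (length(k) == 1L) reflected[k] <- reflected[k] + hist$counts[j]
  }
  surviving <- numeric(nb)
  surviving[pos] <- pmax(hist$counts[pos] - reflected[pos], 0)
  matched <- sum(pmin(hist$counts[pos], reflected[pos]))
  total <- sum(hist$counts)
  noise_fraction <- min(1, (sum(hist$counts[neg]) + matched) / total)
  corrected_mean <- if (sum(surviving) > 0)
    sum(hist$bin_values[pos] * surviving[pos]) / sum(surviving)
  else 0
  list(corrected_mean = corrected_mean, noise_fraction = noise_fraction,
       surviving_counts = surviving)
}

#' Noise-corrected leakage summary per region
#'
#' For each of white matter, grey matter (cortical + deep grey +
#' hippocampus) and hippocampus: the raw ROI mean and the
#' histogram-noise-corrected mean of Ki and vp, with the estimated noise
#' fraction of the Ki histogram.
#'
#' @param patlak A [fit_patlak_volume()] result.
#' @param labels 3D integer label array.
#' @param bins Bin count passed to [build_histogram()] (`NULL` = automatic).
#' @return A `data.frame` of class `roi_summary` with one row per region:
#'   `region`, `n_voxels`, `mean_Ki_raw`, `mean_Ki_corrected`,
#'   `mean_vp_raw`, `mean_vp_corrected`, `noise_fraction`.
#' @export
summarize_roi <- function(patlak, labels, bins = NULL) {
  stopifnot(inherits(patlak, "patlak_result"))
  regions <- c("white_matter", "grey_matter", "hippocampus")
  rows <- lapply(regions, function(r) {
    sel <- labels %in% region_codes(r)
    if (!any(sel)) stop("region missing from label volume: ", r)
    if (!any(is.finite(patlak$Ki_map[sel])))
      stop("region has no fitted voxels: ", r)
    hk <- build_histogram(patlak$Ki_map, labels, r, bins = bins)
    hv <- build_histogram(patlak$vp_map, labels, r, bins = bins)
    ck <- noise_corrected_mean(hk)
    cv <- noise_corrected_mean(hv)
    data.frame(region = r, n_voxels = hk$n_voxels,
               mean_Ki_raw = mean(patlak$Ki_map[sel], na.rm = TRUE),
               mean_Ki_corrected = ck$corrected_mean,
               mean_vp_raw = mean(patlak$vp_map[sel], na.rm = TRUE),
               mean_vp_corrected = cv$corrected_mean,
               noise_fraction = ck$noise_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("roi_summary", class(out))
  out
}
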