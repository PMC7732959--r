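#' Tissue label codes used by the phantom and ROI stages
#'
#' Integer codes of the label volume: background 0, white matter 1,
#' cortical/deep grey matter 2, hippocampus 3, superior sagittal sinus 4.
#' "Grey matter" as an analysis region means cortical and deep grey matter
#' plus hippocampus (codes 2 and 3); the hippocampus is also analysed
#' separately.
#'
#' @return Named integer vector of label codes.
#' @export
tissue_labels <- function() {
  c(background = 0L, white_matter = 1L, grey_matter = 2L,
    hippocampus = 3L, sinus = 4L)
}

# voxel codes belonging to a named analysis region
region_codes <- function(region) {
  switch(region,
         white_matter = 1L,
         grey_matter  = c(2L, 3L),
         hippocampus  = 3L,
         sinus        = 4L,
         stop("unknown region: ", region))
}

# block-shaped label geometry scaled to the grid; sinus is a 2 x 2 column
# through all slices so that even small grids hold >= 20 sinus voxels
default_label_geometry <- function(grid_shape) {
  g <- as.integer(grid_shape)
  lab <- array(0L, dim = g)
  sc <- function(f, n) pmax(1L, pmin(n, as.integer(round(f * n))))
  # white matter: large left/central block
  lab[sc(.15, g[1]):sc(.55, g[1]), sc(.15, g[2]):sc(.80, g[2]),
      sc(.20, g[3]):sc(.85, g[3])] <- 1L
  # grey matter: right block
  lab[sc(.62, g[1]):sc(.90, g[1]), sc(.15, g[2]):sc(.70, g[2]),
      sc(.20, g[3]):sc(.85, g[3])] <- 2L
  # hippocampus: small block inside the white matter territory
  lab[sc(.25, g[1]):sc(.40, g[1]), sc(.25, g[2]):sc(.40, g[2]),
      sc(.35, g[3]):sc(.65, g[3])] <- 3L
  # sinus: posterior 2 x 2 column through all slices
  xs <- sc(.45, g[1]); ys <- sc(.92, g[2])
  lab[xs:min(g[1], xs + 1L), ys:min(g[2], ys + 1L), ] <- 4L
  lab
}

#' Digital phantom specification
#'
#' Geometry, ground-truth parameter maps and noise level of the synthetic
#' dual-time-resolution DCE dataset. The `"desk"` preset plants leakage
#' rates on the order of 1e-3 1/min (the in-vivo medians scaled by 1e3) so
#' that parameter recovery is testable at desk-scale noise; the `"invivo"`
#' preset uses the in-vivo scale itself (WM 1.1e-6, GM 0.9e-6, hippocampus
#' 1.7e-6 1/min), at which recovery demands near-noiseless data. Plasma
#' volume fractions (WM 0.005, GM 0.015, hippocampus 0.010) and T10 values
#' (0.85 / 1.3 / 1.2 s; blood 1.6 s) are typical 3 T figures.
#'
#' @param grid_shape Integer vector of voxels per axis (3 values).
#' @param voxel_size Voxel size in mm per axis.
#' @param preset `"desk"` or `"invivo"` ground-truth leakage scale.
#' @param noise_sd Gaussian signal noise standard deviation (signal units;
#'   the default baseline signal is ~1000).
#' @param seed Integer seed making the dataset deterministic.
#' @param label_map,true_Ki,true_vp,T10_map Optional overrides (3D arrays of
#'   `grid_shape`); defaults are built from the block geometry and preset.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(16, 16, 8), voxel_size = c(2, 2, 5),
                         preset = c("desk", "invivo"), noise_sd = 5, seed = 1,
                         label_map = NULL, true_Ki = NULL, true_vp = NULL,
                         T10_map = NULL) {
  preset <- match.arg(preset)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            length(voxel_size) == 3L, all(voxel_size > 0))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(label_map)) label_map <- default_label_geometry(grid_shape)
  if (!identical(dim(label_map), grid_shape))
    stop("label_map shape does not match grid_shape")
  scale <- if (preset == "desk") 1e-3 else 1e-6
  ki_by_label <- c(0, 1.1, 0.9, 1.7, 0) * scale       # per label code 0..4
  vp_by_label <- c(0, 0.005, 0.015, 0.010, 0.55)      # sinus = plasma fraction
  t10_by_label <- c(0, 0.85, 1.30, 1.20, 1.60)
  if (is.null(true_Ki)) true_Ki <- array(ki_by_label[label_map + 1L],
                                         dim = grid_shape)
  if (is.null(true_vp)) true_vp <- array(vp_by_label[label_map + 1L],
                                         dim = grid_shape)
  if (is.null(T10_map)) T10_map <- array(t10_by_label[label_map + 1L],
                                         dim = grid_shape)
  for (m in list(true_Ki, true_vp, T10_map))
    if (!identical(dim(m), grid_shape)) stop("map shape does not match grid_shape")
  if (any(true_Ki < 0)) stop("true_Ki must be >= 0 everywhere")
  if (any(true_vp < 0 | true_vp >= 1)) stop("true_vp must be in [0, 1)")
  if (any(T10_map[label_map != 0L] <= 0))
    stop("T10 must be > 0 in non-background voxels")
  if (sum(label_map == 4L) < 20L)
    stop("the sinus label must mark at least 20 voxels")
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 preset = preset, noise_sd = noise_sd, seed = as.integer(seed),
                 label_map = label_map, true_Ki = true_Ki, true_vp = true_vp,
                 T10_map = T10_map),
            class = "phantom_spec")
}

# run code with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic dual-time-resolution DCE dataset
#'
#' Builds the noiseless signal of every voxel as the composition of the
#' Patlak forward model and the simulator signal model (tissue voxels), or
#' of the in-vitro calibration forward map applied to the whole-blood
#' concentration `Cp * (1 - hematocrit)` (sinus voxels), then adds
#' independent Gaussian noise per voxel and frame. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param schedule An [acquisition_schedule()].
#' @param signal A [signal_params()]; the default linear model makes the
#'   noiseless simulate/convert/fit chain exactly self-consistent.
#' @param calibration A [vif_calibration()] used for sinus voxels.
#' @param conversion A [conversion_params()]; only `hematocrit` is used
#'   here.
#' @param vif_args Named list of extra arguments for [vif_model()].
#' @return List with 4D arrays `fast` and `slow`, 3D arrays `t1_map`,
#'   `label_map`, `true_Ki`, `true_vp`, the plasma `vif` curve, the time
#'   axis, and the generating `spec`/`schedule`/`signal` objects.
#' @export
generate_phantom_dataset <- function(spec, schedule = acquisition_schedule(),
                                     signal = signal_params(),
                                     calibration = default_vif_calibration(),
                                     conversion = conversion_params(),
                                     vif_args = list()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(schedule, "acq_schedule"))
  t <- make_time_axis(schedule)
  n_fast <- attr(t, "n_fast")
  cp <- do.call(vif_model, c(list(t_min = t,
                                  bolus_arrival_min = schedule$bolus_arrival / 60),
                             vif_args))
  icp <- cumtrapz(t, cp)
  g <- spec$grid_shape
  nvox <- prod(g)
  lab <- as.vector(spec$label_map)
  ki <- as.vector(spec$true_Ki)
  vp <- as.vector(spec$true_vp)
  t10 <- as.vector(spec$T10_map)

  S <- matrix(0, nrow = nvox, ncol = length(t))
  tis <- lab %in% c(1L, 2L, 3L)
  if (any(tis)) {
    # Ct(v, t) = Ki_v * icp_t + vp_v * cp_t, then the signal model per voxel
    Ct <- outer(ki[tis], icp) + outer(vp[tis], cp)
    if (signal$model == "linear") {
      S[tis, ] <- signal$M0 * (1 + signal$r1 * t10[tis] * Ct)
    } else {
      a <- signal$flip_deg * pi / 180
      R1 <- 1 / t10[tis] + signal$r1 * Ct
      E1 <- exp(-signal$TR * R1)
      S[tis, ] <- signal$M0 * sin(a) * (1 - E1) / (1 - cos(a) * E1)
    }
  }
  sin_v <- lab == 4L
  if (any(sin_v)) {
    cb <- cp * (1 - conversion$hematocrit)   # whole-blood concentration
    sb <- calibration_signal(calibration, cb)
    S[sin_v, ] <- matrix(sb, nrow = sum(sin_v), ncol = length(t), byrow = TRUE)
  }
  if (spec$noise_sd > 0) {
    S <- S + with_seed(spec$seed,
                       matrix(stats::rnorm(length(S), sd = spec$noise_sd),
                              nrow = nvox))
  }
  list(fast = array(S[, seq_len(n_fast)], dim = c(g, n_fast)),
       slow = array(S[, -seq_len(n_fast)], dim = c(g, length(t) - n_fast)),
       t1_map = spec$T10_map, label_map = spec$label_map,
       true_Ki = spec$true_Ki, true_vp = spec$true_vp,
       vif = conc_curve(t, cp, compartment = "plasma"),
       times_min = as.numeric(t), n_fast = n_fast,
       spec = spec, schedule = schedule, signal = signal)
}

#' Sinus voxel index list of a label volume
#'
#' @param label_map 3D integer label array.
#' @return Integer matrix (n x 3) of 1-based voxel indices labelled sinus.
#' @export
sinus_voxel_indices <- function(label_map) {
  which(label_map == 4L, arr.ind = TRUE)
}
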