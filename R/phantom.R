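#' Specify a synthetic fMRI phantom
#'
#' A phantom is a small 4D volume in which the voxels of a rectangular ROI
#' carry a smoothly varying mixture of K "target network" time courses, so
#' that each ROI voxel's connectivity to the rest of the (synthetic) brain
#' changes gradually along one spatial axis. The planted gradient coordinate
#' of ROI voxel i is
#'
#'   g_i = 0.5 + theta * (p_i - 0.5),
#'
#' where p_i in \[0,1\] is the voxel's normalized position along
#' `gradient_axis` and theta ("flatness") in (0,1] shrinks the gradient
#' towards its midpoint: theta = 1 gives the full dorsoventral-style
#' topography, smaller theta a flatter (less differentiated) one. Out-of-ROI
#' voxels are arranged as K contiguous slabs, one per network, so the phantom
#' has a known fingerprint structure end to end.
#'
#' @param grid_dims integer X, Y, Z extent of the voxel grid.
#' @param n_timepoints number of volumes T (at least 30).
#' @param tr_seconds repetition time in seconds.
#' @param roi_extent list with integer index vectors `x`, `y`, `z` giving the
#'   axis-aligned ROI box (1-based, strictly inside the grid).
#' @param n_networks number of out-of-ROI target networks K (at least 2).
#' @param gradient_axis axis along which the gradient runs: "x", "y" or "z".
#' @param flatness theta in (0,1].
#' @param noise_sd standard deviation of i.i.d. Gaussian observation noise
#'   added to every in-brain voxel.
#' @param seed integer seed; phantom generation is fully deterministic given
#'   the spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dims = c(12L, 6L, 12L),
                         n_timepoints = 200L,
                         tr_seconds = 2,
                         roi_extent = list(x = 1:6, y = 1:6, z = 2:11),
                         n_networks = 4L,
                         gradient_axis = "z",
                         flatness = 1,
                         noise_sd = 0.5,
                         seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3, all(grid_dims >= 1))
  if (n_timepoints < 30) stopf("n_timepoints must be >= 30, got %d", n_timepoints)
  if (tr_seconds <= 0) stopf("tr_seconds must be positive")
  if (!gradient_axis %in% c("x", "y", "z")) stopf("gradient_axis must be x, y or z")
  if (!(flatness > 0 && flatness <= 1)) stopf("flatness must lie in (0, 1]")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (n_networks < 2) stopf("n_networks must be >= 2")
  ax <- c("x", "y", "z")
  for (a in seq_along(ax)) {
    r <- roi_extent[[ax[a]]]
    if (is.null(r) || length(r) < 1) stopf("roi_extent$%s missing", ax[a])
    if (min(r) < 1 || max(r) > grid_dims[a])
      stopf("roi_extent$%s exceeds the grid", ax[a])
  }
  n_roi <- length(roi_extent$x) * length(roi_extent$y) * length(roi_extent$z)
  if (n_roi < 2) stopf("degenerate ROI: a single voxel cannot carry a gradient")
  # out-of-ROI network slabs live at x > max(roi x) + 1, split along z
  if (max(roi_extent$x) + 2 > grid_dims[1])
    stopf("grid too small in x to host the out-of-ROI network blocks")
  if (grid_dims[3] < n_networks)
    stopf("grid too small in z to host %d network slabs", n_networks)
  structure(list(grid_dims = grid_dims,
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds,
                 roi_extent = roi_extent,
                 n_networks = as.integer(n_networks),
                 gradient_axis = gradient_axis,
                 flatness = flatness,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: grid %s, T = %d, TR = %gs, K = %d, axis = %s, theta = %g, sigma = %g, seed = %d\n",
              paste(x$grid_dims, collapse = "x"), x$n_timepoints, x$tr_seconds,
              x$n_networks, x$gradient_axis, x$flatness, x$noise_sd, x$seed))
  invisible(x)
}

# smoothed-noise network time course: white noise passed through a centred
# moving average of width 3 TRs (circular, so length and stationarity are
# preserved), then standardized. Mimics band-limited BOLD without an HRF.
network_timecourse <- function(n_timepoints) {
  z <- stats::rnorm(n_timepoints)
  s <- as.numeric(stats::filter(z, rep(1 / 3, 3), method = "convolution",
                                sides = 2, circular = TRUE))
  as.numeric(scale(s))
}

# Gaussian connectivity bump of network k at gradient coordinate g.
# The bump SD of 1/K makes adjacent network weights overlap strongly, so the
# fingerprint changes smoothly (rather than in parcel-like steps) along the
# gradient; narrower bumps leave the similarity matrix without long-range
# ordering information and the spectral embedding cannot order the networks.
network_weights <- function(g, n_networks) {
  centres <- seq(0, 1, length.out = n_networks)
  bw <- 1 / n_networks
  sapply(centres, function(ck) exp(-(g - ck)^2 / (2 * bw^2)))
}

#' Generate a synthetic 4D phantom with a planted connection topography
#'
#' ROI voxel i receives sum_k w_k(g_i) * tau_k(t) plus Gaussian noise, where
#' tau_k are independent smoothed-noise network time courses and w_k are
#' Gaussian bumps (SD = 1/(2K)) centred at K equally spaced points on
#' \[0,1\]; the out-of-ROI voxels of network block k receive tau_k(t) plus
#' noise. The call is deterministic given the spec (including its seed).
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `bold` (a `bold_volume`), `roi_mask` and
#'   `brain_mask` (3D logical arrays), and `truth` (class `phantom_truth`:
#'   `gradient_coord` per ROI voxel in canonical voxel order,
#'   `network_assignment` per out-of-ROI in-brain voxel, and the realized
#'   `flatness`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_dims
  T <- spec$n_timepoints
  K <- spec$n_networks

  roi_mask <- array(FALSE, dims)
  roi_mask[spec$roi_extent$x, spec$roi_extent$y, spec$roi_extent$z] <- TRUE

  # K contiguous slabs along z, separated from the ROI by a 1-voxel gap in x
  block_mask <- array(FALSE, dims)
  block_id <- array(0L, dims)
  x_blk <- (max(spec$roi_extent$x) + 2):dims[1]
  z_cut <- floor(seq(0, dims[3], length.out = K + 1))
  for (k in seq_len(K)) {
    z_blk <- (z_cut[k] + 1):z_cut[k + 1]
    block_mask[x_blk, , z_blk] <- TRUE
    block_id[x_blk, , z_blk] <- k
  }
  brain_mask <- roi_mask | block_mask

  roi_idx <- which(roi_mask)
  blk_idx <- which(block_mask)
  V_roi <- length(roi_idx)

  # planted gradient coordinate per ROI voxel (canonical = ascending flat index)
  ijk <- arrayInd(roi_idx, dims)
  a <- match(spec$gradient_axis, c("x", "y", "z"))
  pos <- ijk[, a]
  p <- (pos - min(pos)) / max(1L, diff(range(pos)))
  g <- 0.5 + spec$flatness * (p - 0.5)

  W <- network_weights(g, K)                     # V_roi x K

  data <- with_seed(spec$seed, {
    tau <- sapply(seq_len(K), function(k) network_timecourse(T))  # T x K
    arr <- array(0, c(dims, T))
    roi_ts <- tau %*% t(W)                       # T x V_roi
    blk_ts <- tau[, block_id[blk_idx], drop = FALSE]
    if (spec$noise_sd > 0) {
      roi_ts <- roi_ts + spec$noise_sd * matrix(stats::rnorm(T * V_roi), T)
      blk_ts <- blk_ts + spec$noise_sd * matrix(stats::rnorm(T * length(blk_idx)), T)
    }
    flat <- matrix(0, prod(dims), T)
    flat[roi_idx, ] <- t(roi_ts)
    flat[blk_idx, ] <- t(blk_ts)
    array(flat, c(dims, T))
  })

  bold <- bold_volume(data, affine = diag(c(2, 2, 2, 1)),
                      tr_seconds = spec$tr_seconds)
  truth <- structure(list(gradient_coord = g,
                          network_assignment = block_id[blk_idx],
                          flatness = spec$flatness),
                     class = "phantom_truth")
  list(bold = bold, roi_mask = roi_mask, brain_mask = brain_mask, truth = truth)
}

#' Specify a simulated cohort
#'
#' Each subject receives a flatness value theta_s drawn uniformly from
#' `flatness_range` (shifted down by `group_flatness_shift` in the "case"
#' group) and a behavioural score linearly coupled to it:
#' score_s = intercept + effect_slope * theta_s + N(0, score_noise_sd).
#' Age, sex and site covariates are drawn as specified.
#'
#' @param n_subjects number of subjects (at least 4); split half case /
#'   half control.
#' @param effect_slope slope b of the flatness-to-score coupling.
#' @param score_intercept intercept of the score model.
#' @param score_noise_sd SD of the score noise.
#' @param group_flatness_shift amount subtracted from case-group flatness.
#' @param flatness_range uniform range that theta_s is drawn from.
#' @param age_mean,age_sd age distribution in years.
#' @param male_prop proportion of male subjects.
#' @param n_sites number of acquisition sites.
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 60L,
                        effect_slope = 40,
                        score_intercept = 60,
                        score_noise_sd = 5,
                        group_flatness_shift = 0,
                        flatness_range = c(0.3, 1),
                        age_mean = 17, age_sd = 5,
                        male_prop = 0.68,
                        n_sites = 4L,
                        seed = 1L) {
  if (n_subjects < 4) stopf("n_subjects must be >= 4")
  stopifnot(length(flatness_range) == 2, flatness_range[1] > 0,
            flatness_range[2] <= 1, flatness_range[1] < flatness_range[2])
  structure(list(n_subjects = as.integer(n_subjects),
                 effect_slope = effect_slope,
                 score_intercept = score_intercept,
                 score_noise_sd = score_noise_sd,
                 group_flatness_shift = group_flatness_shift,
                 flatness_range = flatness_range,
                 age_mean = age_mean, age_sd = age_sd,
                 male_prop = male_prop,
                 n_sites = as.integer(n_sites),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a simulated cohort of phantoms with a planted association
#'
#' Draws per-subject flatness, scores and covariates according to `cspec`,
#' then (optionally) materializes one phantom per subject, each from its own
#' RNG stream derived from `(cspec$seed, subject index)` so subjects are
#' statistically decoupled.
#'
#' @param pspec a [phantom_spec()] used as the template for every subject;
#'   its `flatness` and `seed` are overridden per subject.
#' @param cspec a [cohort_spec()].
#' @param materialize if `FALSE`, return per-subject phantom specs instead of
#'   generated volumes (the bundles then carry `spec` only).
#' @return list with `bundles` (per subject: `subject_id`, `spec`, and when
#'   materialized the elements of [generate_phantom()]) and `cohort`, a
#'   data.frame with columns subject_id, group, score, age, sex, site and the
#'   realized flatness.
#' @export
generate_cohort <- function(pspec, cspec, materialize = TRUE) {
  stopifnot(inherits(pspec, "phantom_spec"), inherits(cspec, "cohort_spec"))
  n <- cspec$n_subjects
  group <- rep(c("control", "case"), length.out = n)
  tab <- with_seed(cspec$seed, {
    theta <- stats::runif(n, cspec$flatness_range[1], cspec$flatness_range[2])
    theta[group == "case"] <- theta[group == "case"] - cspec$group_flatness_shift
    theta <- pmin(pmax(theta, 0.01), 1)
    score <- cspec$score_intercept + cspec$effect_slope * theta +
      stats::rnorm(n, sd = cspec$score_noise_sd)
    data.frame(subject_id = sprintf("sub-%03d", seq_len(n)),
               group = group,
               score = score,
               age = stats::rnorm(n, cspec$age_mean, cspec$age_sd),
               sex = ifelse(stats::runif(n) < cspec$male_prop, "M", "F"),
               site = sprintf("site%d", sample.int(cspec$n_sites, n, replace = TRUE)),
               flatness = theta,
               stringsAsFactors = FALSE)
  })
  bundles <- lapply(seq_len(n), function(s) {
    sp <- pspec
    sp$flatness <- tab$flatness[s]
    sp$seed <- subject_seed(cspec$seed, s)
    b <- list(subject_id = tab$subject_id[s], spec = sp)
    if (materialize) b <- c(b, generate_phantom(sp))
    b
  })
  list(bundles = bundles, cohort = tab)
}

#' Write a phantom bundle to disk
#'
#' Writes the BOLD volume, both masks (NIfTI), and the ground-truth sidecar
#' (JSON) plus, when given a cohort table, the cohort TSV.
#'
#' @param bundle a single-subject bundle from [generate_phantom()] /
#'   [generate_cohort()].
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return invisibly, the named vector of paths written.
#' @export
write_phantom <- function(bundle, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(bold = file.path(dir, paste0(prefix, "_bold.nii.gz")),
             roi = file.path(dir, paste0(prefix, "_roi.nii.gz")),
             brain = file.path(dir, paste0(prefix, "_brain.nii.gz")),
             truth = file.path(dir, paste0(prefix, "_truth.json")))
  write_volume(bundle$bold, paths["bold"])
  write_mask(bundle$roi_mask, bundle$bold$affine, paths["roi"])
  write_mask(bundle$brain_mask, bundle$bold$affine, paths["brain"])
  jsonlite::write_json(list(gradient_coord = bundle$truth$gradient_coord,
                            network_assignment = bundle$truth$network_assignment,
                            flatness = bundle$truth$flatness),
                       paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
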