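#' Regress nuisance signals out of a time-by-voxel matrix
#'
#' Ordinary-least-squares removal of confound time series (e.g. white-matter
#' and CSF signals): the returned residuals are orthogonal to the confounds
#' and to the intercept, which is always included.
#'
#' @param data T x V numeric matrix.
#' @param confounds T x q numeric matrix (or NULL for intercept only).
#' @return T x V residual matrix.
#' @export
regress_nuisance <- function(data, confounds = NULL) {
  data <- as.matrix(data)
  T <- nrow(data)
  X <- cbind(intercept = rep(1, T), confounds)
  if (!is.null(confounds) && nrow(as.matrix(confounds)) != T)
    stopf("confounds have %d rows but data has %d", nrow(as.matrix(confounds)), T)
  if (anyNA(X) || any(!is.finite(X))) stopf("non-finite confound values")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]] %||% "<unnamed>"
    stopf("confounds are rank-deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  qr.resid(qrX, data)
}

# discrete-cosine drift basis: column j has frequency j / (2 * T * TR) Hz
dct_basis <- function(n_timepoints, n_funcs) {
  t <- seq_len(n_timepoints) - 0.5
  sapply(seq_len(n_funcs), function(j) cos(pi * j * t / n_timepoints))
}

#' High-pass filter by discrete-cosine drift removal
#'
#' Regresses out a DCT basis spanning all frequencies strictly below
#' `cutoff_hz` (plus the constant), the standard drift model for removing
#' very-low-frequency scanner trends. Unlike a recursive filter it has no
#' edge transients; sinusoids well above the cutoff pass essentially
#' unattenuated.
#'
#' @param data T x V numeric matrix.
#' @param cutoff_hz high-pass cutoff in Hz (default 0.01).
#' @param tr_seconds repetition time in seconds.
#' @return T x V filtered matrix (mean removed).
#' @export
highpass_filter <- function(data, cutoff_hz = 0.01, tr_seconds) {
  data <- as.matrix(data)
  T <- nrow(data)
  if (T < 3) stopf("too few time points (%d) to filter", T)
  nyquist <- 1 / (2 * tr_seconds)
  if (cutoff_hz >= nyquist)
    stopf("cutoff %g Hz is not below the Nyquist frequency %g Hz", cutoff_hz, nyquist)
  n_drift <- floor(2 * T * tr_seconds * cutoff_hz)
  X <- cbind(1, if (n_drift >= 1) dct_basis(T, n_drift))
  if (ncol(X) >= T - 1) stopf("drift basis leaves fewer than 2 usable frames")
  qr.resid(qr(X), data)
}

#' Nuisance regression and high-pass filtering in a single design
#'
#' Projects the data onto the orthogonal complement of the concatenated
#' design \[intercept | confounds | DCT drift basis\] in one OLS step.
#' Chaining [regress_nuisance()] and [highpass_filter()] is only an
#' approximation to this unless the confounds happen to be orthogonal to the
#' drift basis, so the one-step projection is the preferred preprocessing
#' path.
#'
#' @param data T x V numeric matrix.
#' @param confounds optional T x q confound matrix.
#' @param cutoff_hz high-pass cutoff in Hz (NULL skips drift removal).
#' @param tr_seconds repetition time in seconds.
#' @return T x V residual matrix.
#' @export
preprocess_series <- function(data, confounds = NULL, cutoff_hz = 0.01,
                              tr_seconds = 1) {
  data <- as.matrix(data)
  T <- nrow(data)
  drift <- NULL
  if (!is.null(cutoff_hz)) {
    if (cutoff_hz >= 1 / (2 * tr_seconds))
      stopf("cutoff %g Hz is not below the Nyquist frequency", cutoff_hz)
    n_drift <- floor(2 * T * tr_seconds * cutoff_hz)
    if (n_drift >= 1) drift <- dct_basis(T, n_drift)
  }
  regress_nuisance(data, cbind(confounds, drift))
}

#' Framewise displacement from six rigid-body motion parameters
#'
#' Power's formulation: FD_t = sum |delta translations| +
#' head_radius * sum |delta rotations|, with FD_1 = 0. Rotations (radians)
#' are converted to arc length at `head_radius_mm`.
#'
#' @param motion_params T x 6 matrix of realignment parameters.
#' @param head_radius_mm sphere radius for the rotation arc, default 50 mm.
#' @param rotations_first if `TRUE` (default) columns are 3 rotations then 3
#'   translations (FSL convention); otherwise translations first.
#' @return object of class `motion_summary` with `fd_series`, `fd_mean`,
#'   `fd_max`.
#' @export
framewise_displacement <- function(motion_params, head_radius_mm = 50,
                                   rotations_first = TRUE) {
  mp <- as.matrix(motion_params)
  if (ncol(mp) != 6) stopf("motion parameters must have 6 columns, got %d", ncol(mp))
  if (any(!is.finite(mp))) stopf("non-finite motion parameters")
  rot <- if (rotations_first) mp[, 1:3, drop = FALSE] else mp[, 4:6, drop = FALSE]
  trans <- if (rotations_first) mp[, 4:6, drop = FALSE] else mp[, 1:3, drop = FALSE]
  d <- function(m) abs(apply(m, 2, function(col) c(0, diff(col))))
  fd <- rowSums(d(trans)) + head_radius_mm * rowSums(d(rot))
  structure(list(fd_series = fd, fd_mean = mean(fd), fd_max = max(fd)),
            class = "motion_summary")
}

#' Default subject-exclusion thresholds
#'
#' Mean FD above 0.7 mm, maximum FD above 3.8 mm (one voxel size), ROI
#' variance below the floor, or reference correlation below 0.5. All
#' comparisons are strict, so a subject sitting exactly at a threshold is
#' retained.
#'
#' @param fd_mean_mm,fd_max_mm motion thresholds in mm.
#' @param variance_floor minimum acceptable ROI voxel variance.
#' @param reference_r_min minimum acceptable correlation with the reference
#'   connectopy.
#' @return named list of thresholds.
#' @export
qc_thresholds <- function(fd_mean_mm = 0.7, fd_max_mm = 3.8,
                          variance_floor = 1e-6, reference_r_min = 0.5) {
  list(fd_mean_mm = fd_mean_mm, fd_max_mm = fd_max_mm,
       variance_floor = variance_floor, reference_r_min = reference_r_min)
}

#' Apply subject-level exclusion rules
#'
#' A subject is excluded iff any rule fires; every exclusion carries its
#' reason(s). Rules: `motion_mean` (fd_mean > threshold), `motion_max`
#' (fd_max > threshold), `roi_variance` (minimum ROI voxel variance <
#' floor), `reference_correlation` (post-alignment r < minimum, only checked
#' when a reference correlation is supplied).
#'
#' @param cohort data.frame with a `subject_id` column.
#' @param summaries named list of [framewise_displacement()] results, one per
#'   subject.
#' @param roi_variances named numeric vector: minimum ROI voxel variance per
#'   subject.
#' @param reference_rs optional named numeric vector of reference
#'   correlations per subject.
#' @param thresholds a [qc_thresholds()] list.
#' @return list with `retained` (filtered cohort) and `qc`, a data.frame of
#'   per-subject QC results (passed flag plus one logical column per rule).
#' @export
apply_exclusions <- function(cohort, summaries, roi_variances,
                             reference_rs = NULL,
                             thresholds = qc_thresholds()) {
  ids <- cohort$subject_id
  missing <- setdiff(ids, names(summaries))
  if (length(missing) > 0)
    stopf("no motion summary for subject(s): %s", paste(missing, collapse = ", "))
  missing <- setdiff(ids, names(roi_variances))
  if (length(missing) > 0)
    stopf("no ROI variance for subject(s): %s", paste(missing, collapse = ", "))
  qc <- do.call(rbind, lapply(ids, function(id) {
    s <- summaries[[id]]
    fails <- c(motion_mean = s$fd_mean > thresholds$fd_mean_mm,
               motion_max = s$fd_max > thresholds$fd_max_mm,
               roi_variance = roi_variances[[id]] < thresholds$variance_floor,
               reference_correlation = if (is.null(reference_rs)) FALSE
                 else reference_rs[[id]] < thresholds$reference_r_min)
    data.frame(subject_id = id, passed = !any(fails),
               motion_mean = unname(fails["motion_mean"]),
               motion_max = unname(fails["motion_max"]),
               roi_variance = unname(fails["roi_variance"]),
               reference_correlation = unname(fails["reference_correlation"]),
               reasons = paste(names(fails)[fails], collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  list(retained = cohort[qc$passed, , drop = FALSE], qc = qc)
}

#' Erode a binary mask with the 6-connected structuring element
#'
#' A voxel survives one iteration iff all six face neighbours are inside the
#' mask (voxels beyond the grid edge count as outside). Used for the
#' edge-effect sensitivity analysis on eroded ROIs.
#'
#' @param mask 3D logical/binary array.
#' @param iterations number of erosion passes (>= 1).
#' @return 3D logical array, a subset of the input.
#' @export
erode_mask <- function(mask, iterations = 1L) {
  if (iterations < 1) stopf("iterations must be >= 1")
  m <- array(mask != 0, dim(mask))
  d <- dim(m)
  shift <- function(a, axis, by) {
    out <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    if (by == 1) { dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1) }
    else { dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (it in seq_len(iterations)) {
    keep <- m
    for (axis in 1:3) for (by in c(1, -1)) keep <- keep & shift(m, axis, by)
    if (!any(keep)) stopf("erosion would empty the mask at iteration %d", it)
    m <- keep
  }
  m
}
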