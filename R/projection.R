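#' Project ROI spatial maps onto the whole brain by dual regression
#'
#' Stage 1 regresses, at every timepoint, the ROI voxel values onto the
#' demeaned spatial map(s) (plus an intercept across voxels), yielding one
#' time course per map; each time course is variance-normalized so the
#' stage-2 coefficients are invariant to the spatial maps' scale. Stage 2
#' regresses every brain voxel's time series onto an intercept plus the
#' time courses, yielding one whole-brain coefficient image per map.
#'
#' @param brain_data T x V_brain matrix of (standardized) in-brain time
#'   series.
#' @param roi_maps V_roi x M matrix of spatial maps over the ROI voxels (a
#'   single map may be given as a vector or `connectopy`).
#' @param roi_index integer positions of the ROI voxels among the columns of
#'   `brain_data`.
#' @return list with `timecourses` (T x M, variance-normalized) and `maps`
#'   (V_brain x M matrix of projection values).
#' @export
dual_regression <- function(brain_data, roi_maps, roi_index) {
  Y <- as.matrix(brain_data)
  if (inherits(roi_maps, "connectopy")) roi_maps <- roi_maps$values
  S <- as.matrix(roi_maps)
  M <- ncol(S)
  if (max(roi_index) > ncol(Y) || min(roi_index) < 1)
    stopf("roi_index out of range")
  if (nrow(S) != length(roi_index))
    stopf("roi_maps has %d rows but roi_index selects %d voxels",
          nrow(S), length(roi_index))
  Sd <- sweep(S, 2, colMeans(S))                 # demean across voxels
  X1 <- cbind(1, Sd)
  if (qr(X1)$rank < ncol(X1))
    stopf("rank-deficient spatial design after demeaning")
  # stage 1: per-timepoint OLS across ROI voxels
  B1 <- solve(crossprod(X1), crossprod(X1, t(Y[, roi_index, drop = FALSE])))
  tc <- t(B1[-1, , drop = FALSE])                # T x M
  sds <- apply(tc, 2, stats::sd)
  # numerically-zero time courses (map orthogonal to the data) stay zero
  # instead of being blown up by the variance normalization
  nz <- sds > 1e-10 * sqrt(mean(Y[, roi_index]^2))
  tc[, !nz] <- 0
  tc[, nz] <- sweep(tc[, nz, drop = FALSE], 2, sds[nz], "/")
  # stage 2: per-voxel OLS over time; degenerate (all-zero) time courses map to 0
  maps <- matrix(0, ncol(Y), M)
  if (any(nz)) {
    X2 <- cbind(1, tc[, nz, drop = FALSE])
    B2 <- solve(crossprod(X2), crossprod(X2, Y))
    maps[, nz] <- t(B2[-1, , drop = FALSE])      # V_brain x M
  }
  list(timecourses = tc, maps = maps)
}
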