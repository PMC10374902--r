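#' Standardize each voxel's time series
#'
#' Columns are scaled to mean 0 and unit sample variance (denominator n-1),
#' the precondition for computing correlations as inner products downstream.
#'
#' @param data T x V numeric matrix.
#' @return T x V standardized matrix.
#' @export
standardize <- function(data) {
  data <- as.matrix(data)
  sds <- apply(data, 2, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad) > 0)
    stopf("zero-variance voxel column(s): %s", paste(bad, collapse = ", "))
  scale(data)[, , drop = FALSE]
}

#' Lossless SVD reduction of out-of-ROI time series
#'
#' Replaces the (typically huge) time-by-voxel matrix of out-of-ROI signals
#' by `U %*% S` from its economy SVD, keeping all components with singular
#' value above `1e-10 * s_max`. The reduction is lossless for every
#' downstream quantity that depends on the voxel time series only through
#' inner products: correlations with the retained components preserve the
#' full connectivity-fingerprint geometry exactly (rotation invariance of
#' the Gram matrix).
#'
#' @param out_roi_data T x N standardized matrix.
#' @return T x C matrix of component time series, C <= min(T-1, N), with the
#'   kept right singular vectors (N x C) attached as attribute `rotation`:
#'   voxel-space covariance fingerprints are recovered exactly as
#'   component-space fingerprints times `t(rotation)`.
#' @export
svd_reduce <- function(out_roi_data) {
  X <- as.matrix(out_roi_data)
  if (all(X == 0)) stopf("all-zero input to svd_reduce")
  s <- svd(X)
  keep <- s$d > 1e-10 * s$d[1]
  structure(s$u[, keep, drop = FALSE] %*% diag(s$d[keep], sum(keep)),
            rotation = s$v[, keep, drop = FALSE])
}

#' Connectivity fingerprints of ROI voxels
#'
#' Entry (i, c) is the Pearson correlation between ROI voxel i's time series
#' and reference component c's time series.
#'
#' @param roi_data T x V_roi standardized matrix.
#' @param components T x C matrix of reference time series (e.g. from
#'   [svd_reduce()]).
#' @return V_roi x C fingerprint matrix.
#' @export
compute_fingerprints <- function(roi_data, components) {
  roi_data <- as.matrix(roi_data); components <- as.matrix(components)
  if (nrow(roi_data) != nrow(components))
    stopf("time dimensions differ: %d vs %d", nrow(roi_data), nrow(components))
  csd <- apply(components, 2, stats::sd)
  if (any(csd == 0)) stopf("zero-variance component(s): %s",
                           paste(which(csd == 0), collapse = ", "))
  fp <- stats::cor(roi_data, components)
  fp[fp > 1] <- 1; fp[fp < -1] <- -1
  fp
}

#' Eta-squared similarity between fingerprint profiles
#'
#' For profiles a, b over C components, with m_i = (a_i + b_i)/2 and M the
#' mean of the m_i,
#' eta2(a, b) = 1 - sum_i ((a_i - m_i)^2 + (b_i - m_i)^2) /
#'                  sum_i ((a_i - M)^2 + (b_i - M)^2),
#' i.e. one minus within-pair over total variance: 1 for identical profiles,
#' 0 for maximally dissimilar ones.
#'
#' @param fp V x C fingerprint matrix (rows are profiles).
#' @return V x V symmetric similarity matrix with unit diagonal, entries in
#'   \[0, 1\].
#' @export
eta2_similarity <- function(fp) {
  fp <- as.matrix(fp)
  V <- nrow(fp); C <- ncol(fp)
  if (V < 2) stopf("need at least 2 profiles")
  rs <- rowSums(fp)
  rq <- rowSums(fp^2)
  # within-pair numerator: sum_i (a_i-m_i)^2 + (b_i-m_i)^2 = ||a-b||^2 / 2
  d2 <- outer(rq, rq, "+") - 2 * tcrossprod(fp)
  Mbar <- outer(rs, rs, "+") / (2 * C)
  den <- outer(rq, rq, "+") - 2 * Mbar * outer(rs, rs, "+") + 2 * C * Mbar^2
  if (any(den[upper.tri(den)] <= .Machine$double.eps * C))
    stopf("constant identical profiles give a zero eta-squared denominator")
  eta <- 1 - 0.5 * d2 / den
  diag(eta) <- 1
  eta[eta < 0] <- 0; eta[eta > 1] <- 1
  (eta + t(eta)) / 2
}

#' Laplacian eigenmaps of a similarity matrix
#'
#' Builds the dense weighted graph W (similarity with zeroed diagonal),
#' checks connectivity, and solves the generalized eigenproblem
#' L v = lambda D v with L = D - W (random-walk normalization) via the
#' symmetrically normalized Laplacian. Eigenvalues are sorted ascending, the
#' trivial constant eigenvector (lambda ~ 0) is discarded, and the next
#' `n_maps` eigenvectors are returned min-max scaled to \[0, 1\] — the
#' connection topographies, in order of importance.
#'
#' @param sim V x V symmetric similarity matrix (e.g. [eta2_similarity()]).
#' @param n_maps number of non-trivial maps to return.
#' @param knn optional k for symmetrized k-nearest-neighbour sparsification
#'   of the graph; `NULL` (default) keeps the dense graph.
#' @return list of `connectopy` objects, each with `values` (scaled to
#'   \[0,1\]), `eigenvalue`, `rank` (1 = primary) and a `degenerate` flag set
#'   when the first two non-trivial eigenvalues nearly coincide.
#' @export
laplacian_eigenmaps <- function(sim, n_maps = 1L, knn = NULL) {
  W <- as.matrix(sim)
  V <- nrow(W)
  stopifnot(ncol(W) == V, n_maps >= 1)
  diag(W) <- 0
  if (!is.null(knn)) {
    keep <- matrix(FALSE, V, V)
    for (i in seq_len(V)) {
      nb <- order(W[i, ], decreasing = TRUE)[seq_len(min(knn, V - 1))]
      keep[i, nb] <- TRUE
    }
    keep <- keep | t(keep)        # symmetrized kNN
    W[!keep] <- 0
  }
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1)
    stopf("similarity graph is disconnected (component sizes: %s)",
          paste(comp$csize, collapse = ", "))
  D <- rowSums(W)
  dhalf <- 1 / sqrt(D)
  # L v = lambda D v  <=>  (I - D^-1/2 W D^-1/2) u = lambda u, v = D^-1/2 u
  A <- (dhalf %o% dhalf) * W
  Lsym <- diag(V) - (A + t(A)) / 2
  e <- eigen(Lsym, symmetric = TRUE)
  ord <- order(e$values)               # ascending
  lambda <- e$values[ord]
  vecs <- (dhalf * e$vectors)[, ord, drop = FALSE]
  cv <- apply(vecs, 2, function(v) stats::sd(v) / max(abs(mean(v)), 1e-300))
  trivial <- lambda < 1e-10 & cv < 1e-6
  keep_idx <- which(!trivial)
  if (length(keep_idx) < n_maps)
    stopf("only %d non-trivial eigenvectors available", length(keep_idx))
  keep_idx <- keep_idx[seq_len(n_maps)]
  degenerate <- FALSE
  nt <- which(!trivial)
  if (length(nt) >= 2 &&
      abs(lambda[nt[2]] - lambda[nt[1]]) < 1e-6 * max(lambda[nt[1]], 1e-300)) {
    degenerate <- TRUE
    warnf("near-degenerate leading eigenvalues (%.3e, %.3e); primary map may be unstable",
          lambda[nt[1]], lambda[nt[2]])
  }
  L <- diag(D) - W
  out <- vector("list", n_maps)
  for (m in seq_along(keep_idx)) {
    j <- keep_idx[m]
    v <- vecs[, j]
    resid <- max(abs(L %*% v - lambda[j] * D * v))
    if (resid > 1e-8)
      stopf("eigenpair residual %.2e exceeds 1e-8", resid)
    out[[m]] <- connectopy(values = (v - min(v)) / (max(v) - min(v)),
                           eigenvalue = lambda[j], rank = m,
                           degenerate = degenerate)
  }
  out
}

#' Construct a connectopy object
#'
#' @param values per-ROI-voxel map scaled to \[0, 1\].
#' @param eigenvalue generalized eigenvalue of the map.
#' @param rank which non-trivial eigenvector (1 = primary).
#' @param roi,condition optional tags (ROI/hemisphere label, rest or task).
#' @param degenerate flag for near-degenerate leading eigenvalues.
#' @param qc_pass,reference_r alignment QC status and reference correlation,
#'   filled by [align_connectopy()].
#' @return object of class `connectopy`.
#' @export
connectopy <- function(values, eigenvalue = NA_real_, rank = 1L,
                       roi = NA_character_, condition = NA_character_,
                       degenerate = FALSE, qc_pass = NA, reference_r = NA_real_) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stopf("non-finite connectopy values")
  structure(list(values = values, eigenvalue = eigenvalue, rank = rank,
                 roi = roi, condition = condition, degenerate = degenerate,
                 qc_pass = qc_pass, reference_r = reference_r),
            class = "connectopy")
}

#' @export
print.connectopy <- function(x, ...) {
  cat(sprintf("connectopy: %d voxels, rank %d, lambda = %.4g%s%s\n",
              length(x$values), x$rank, x$eigenvalue,
              if (isTRUE(x$degenerate)) " [degenerate]" else "",
              if (!is.na(x$reference_r)) sprintf(", reference r = %.3f", x$reference_r) else ""))
  invisible(x)
}

#' Align a connectopy to a reference map
#'
#' The eigenvector sign is arbitrary, so the map is flipped (v -> 1 - v)
#' when it anti-correlates with the reference. The post-flip Pearson
#' correlation doubles as a quality score: maps correlating below
#' `r_min` with the reference fail QC.
#'
#' @param conn a `connectopy`.
#' @param reference per-voxel reference map on the same voxel support.
#' @param r_min QC threshold on the post-flip correlation (default 0.5).
#' @return the (possibly flipped) `connectopy` with `reference_r` and
#'   `qc_pass` filled in.
#' @export
align_connectopy <- function(conn, reference, r_min = 0.5) {
  stopifnot(inherits(conn, "connectopy"))
  reference <- as.numeric(reference)
  if (length(reference) != length(conn$values))
    stopf("reference has %d voxels, connectopy has %d",
          length(reference), length(conn$values))
  if (stats::sd(reference) == 0) stopf("constant reference map")
  r <- stats::cor(conn$values, reference)
  if (r < 0) {
    conn$values <- 1 - conn$values
    r <- -r
  }
  conn$reference_r <- r
  conn$qc_pass <- r >= r_min
  conn
}

#' Voxel-wise spatial correlation between two maps
#'
#' @param map_a,map_b numeric vectors or 3D arrays of per-voxel values.
#' @param mask optional logical vector/array selecting the voxels to
#'   compare; by default all finite positions of both maps.
#' @return Pearson correlation over the in-mask voxels.
#' @export
spatial_correlation <- function(map_a, map_b, mask = NULL) {
  a <- as.numeric(map_a); b <- as.numeric(map_b)
  if (length(a) != length(b)) stopf("maps differ in length")
  sel <- if (is.null(mask)) is.finite(a) & is.finite(b) else as.logical(mask)
  a <- a[sel]; b <- b[sel]
  if (length(a) == 0) stopf("empty mask")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stopf("constant map within mask")
  stats::cor(a, b)
}

#' Estimate connectopies from ROI and out-of-ROI time series
#'
#' Convenience wrapper chaining the full gradient-estimation path:
#' standardize both matrices, reduce the out-of-ROI data by lossless SVD,
#' correlate to get fingerprints, build the eta-squared similarity and run
#' Laplacian eigenmaps.
#'
#' @param roi_data T x V_roi matrix of ROI voxel time series.
#' @param out_data T x N matrix of out-of-ROI time series.
#' @param n_maps number of connectopies to return (default 1, the primary).
#' @param knn optional graph sparsification, see [laplacian_eigenmaps()].
#' @return list of `connectopy` objects.
#' @export
estimate_connectopy <- function(roi_data, out_data, n_maps = 1L, knn = NULL) {
  roi_s <- standardize(roi_data)
  out_s <- standardize(out_data)
  comp <- svd_reduce(out_s)
  fp <- compute_fingerprints(roi_s, comp)
  sim <- eta2_similarity(fp)
  laplacian_eigenmaps(sim, n_maps = n_maps, knn = knn)
}
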