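#' Build a trend-surface polynomial basis over ROI voxel coordinates
#'
#' Coordinates are standardized per axis (mean 0, SD 1) before powering, so
#' coefficients are unit-free and comparable across subjects regardless of
#' voxel size or ROI position. The design holds per-axis monomials only
#' (no cross terms), grouped by power: 1, x, y, z, x^2, y^2, z^2, ...,
#' giving 1 + 3k columns at order k (18 non-intercept terms at order 6).
#' An axis that is constant within the ROI (a one-voxel-thick slab) is
#' dropped with a warning rather than producing a zero column.
#'
#' @param voxel_coords V x 3 matrix of voxel coordinates (grid indices or
#'   world mm; both standardize to the same design up to sign).
#' @param order polynomial order k >= 1.
#' @return object of class `tsm_basis`: `design`, `order`, `terms` (term
#'   names x1..xk, y1..yk, z1..zk), `axes` (axis of each column),
#'   `dropped_axes`, and the standardization centres/scales.
#' @export
build_basis <- function(voxel_coords, order) {
  coords <- as.matrix(voxel_coords)
  stopifnot(ncol(coords) == 3, order >= 1)
  axes <- c("x", "y", "z")
  ctr <- colMeans(coords)
  scl <- apply(coords, 2, stats::sd)
  degenerate <- scl == 0
  if (any(degenerate))
    warnf("axis constant within ROI, dropping its terms: %s",
          paste(axes[degenerate], collapse = ", "))
  if (all(degenerate)) stopf("all axes degenerate")
  std <- sweep(sweep(coords, 2, ifelse(degenerate, 0, ctr)), 2,
               ifelse(degenerate, 1, scl), "/")
  cols <- list(); term_names <- character(); term_axes <- character()
  for (p in seq_len(order)) {
    for (a in which(!degenerate)) {
      cols[[length(cols) + 1]] <- std[, a]^p
      term_names <- c(term_names, paste0(axes[a], p))
      term_axes <- c(term_axes, axes[a])
    }
  }
  design <- cbind(1, do.call(cbind, cols))
  colnames(design) <- c("intercept", term_names)
  if (nrow(design) < ncol(design))
    stopf("%d voxels cannot support %d basis columns", nrow(design), ncol(design))
  structure(list(design = design, order = as.integer(order),
                 terms = term_names, axes = term_axes,
                 dropped_axes = axes[degenerate],
                 centre = ctr, scale = scl),
            class = "tsm_basis")
}

#' Fit a trend-surface model to a connectopy
#'
#' Ordinary least squares of the per-voxel map on the polynomial basis.
#' BIC = n log(RSS/n) + p log(n), where p counts the intercept, the
#' polynomial coefficients and the noise variance; EV = 1 - RSS/TSS. A
#' numerically rank-deficient design raises an error; a merely
#' ill-conditioned one (condition number above 1e10 at high order) falls
#' back to a ridge solve with lambda = 1e-8.
#'
#' @param connectopy a `connectopy` object or plain numeric per-voxel map.
#' @param basis a [build_basis()] result with matching voxel count.
#' @return object of class `tsm_model`: `order`, `intercept`,
#'   `coefficients` (named by term), `bic`, `explained_variance`,
#'   `residual_ss`, `fitted`, `residuals`.
#' @export
fit_tsm <- function(connectopy, basis) {
  y <- if (inherits(connectopy, "connectopy")) connectopy$values else as.numeric(connectopy)
  stopifnot(inherits(basis, "tsm_basis"))
  X <- basis$design
  if (length(y) != nrow(X))
    stopf("map has %d voxels, basis has %d", length(y), nrow(X))
  if (any(!is.finite(y))) stopf("non-finite map values")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stopf("rank-deficient trend-surface design (rank %d < %d columns)",
          qrX$rank, ncol(X))
  d <- svd(X, nu = 0, nv = 0)$d
  if (d[1] / d[length(d)] > 1e10) {
    beta <- solve(crossprod(X) + 1e-8 * diag(ncol(X)), crossprod(X, y))
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qrX, y)
  }
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  n <- length(y)
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  p <- ncol(X) + 1  # + noise variance
  # relative floor keeps BIC finite and makes exactly fitting nested models
  # tie on the likelihood term, so the parsimony penalty picks the lowest
  # order rather than float noise in a ~1e-30 residual
  bic <- n * log(max(rss, 1e-12 * tss, 1e-300) / n) + p * log(n)
  structure(list(order = basis$order,
                 intercept = unname(beta[1]),
                 coefficients = stats::setNames(beta[-1], basis$terms),
                 bic = bic,
                 explained_variance = 1 - rss / tss,
                 residual_ss = rss,
                 fitted = fitted, residuals = resid),
            class = "tsm_model")
}

#' @export
print.tsm_model <- function(x, ...) {
  cat(sprintf("tsm_model: order %d, %d terms, EV = %.4f, BIC = %.2f\n",
              x$order, length(x$coefficients), x$explained_variance, x$bic))
  invisible(x)
}

#' Choose the trend-surface order by BIC
#'
#' Fits orders 1..`max_order` and picks the global BIC minimum (ties broken
#' toward the lower order). The full BIC/EV table is returned so the
#' parsimony-versus-fit trade-off can be audited; by the nesting of the
#' bases, EV is non-decreasing in the order, so the BIC minimum is the point
#' where extra explained variance stops paying for extra parameters.
#'
#' @param connectopy a `connectopy` or numeric per-voxel map.
#' @param voxel_coords V x 3 coordinate matrix.
#' @param max_order largest order to consider.
#' @return list with `order` (chosen), `table` (data.frame of order, bic,
#'   explained_variance, n_terms), and `model`, the fitted `tsm_model` at
#'   the chosen order.
#' @export
select_order <- function(connectopy, voxel_coords, max_order = 6L) {
  stopifnot(max_order >= 1)
  fits <- lapply(seq_len(max_order), function(k)
    tryCatch(fit_tsm(connectopy, build_basis(voxel_coords, k)),
             error = function(e) NULL))
  feasible <- !vapply(fits, is.null, logical(1))
  if (!any(feasible)) stopf("no feasible trend-surface order up to %d", max_order)
  if (!all(feasible))
    warnf("order(s) %s infeasible for this ROI geometry (rank-deficient design)",
          paste(which(!feasible), collapse = ", "))
  num <- function(f, what) if (is.null(f)) NA_real_ else f[[what]]
  tab <- data.frame(order = seq_len(max_order),
                    bic = vapply(fits, num, numeric(1), "bic"),
                    explained_variance = vapply(fits, num, numeric(1),
                                                "explained_variance"),
                    n_terms = vapply(fits, function(f)
                      if (is.null(f)) NA_integer_ else length(f$coefficients),
                      integer(1)))
  best <- which.min(tab$bic)  # first minimum = lowest order on ties; NAs skipped
  list(order = tab$order[best], table = tab, model = fits[[best]])
}

#' Reconstruct a per-voxel map from trend-surface coefficients
#'
#' @param model a `tsm_model`.
#' @param basis the [build_basis()] to evaluate on; its order and terms must
#'   match the model.
#' @return numeric per-voxel map `design %*% c(intercept, coefficients)`.
#' @export
reconstruct <- function(model, basis) {
  stopifnot(inherits(model, "tsm_model"), inherits(basis, "tsm_basis"))
  if (model$order != basis$order)
    stopf("model order %d does not match basis order %d", model$order, basis$order)
  if (!identical(names(model$coefficients), basis$terms))
    stopf("model terms do not match basis terms")
  drop(basis$design %*% c(model$intercept, model$coefficients))
}

#' Root-mean-square error between two coefficient vectors
#'
#' Optionally restricted to the terms of one or more axes (e.g. the z-axis
#' terms, the direction of the dominant gradient).
#'
#' @param c1,c2 named coefficient vectors with a common term layout
#'   (names like x1, y3, z6).
#' @param axis_filter optional character subset of c("x", "y", "z").
#' @return sqrt(mean((c1 - c2)^2)) over the selected terms.
#' @export
rmse_coefficients <- function(c1, c2, axis_filter = NULL) {
  if (length(c1) != length(c2)) stopf("coefficient vectors differ in length")
  if (!is.null(axis_filter)) {
    nm <- names(c1) %||% names(c2)
    if (is.null(nm)) stopf("axis filtering requires named coefficients")
    sel <- substr(nm, 1, 1) %in% axis_filter
    if (!any(sel)) stopf("axis filter selects no terms")
    c1 <- c1[sel]; c2 <- c2[sel]
  }
  sqrt(mean((as.numeric(c1) - as.numeric(c2))^2))
}
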