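# shared fixtures and independent oracles

# small, fast phantom: 4x4x8 ROI (128 voxels), 3 networks, T = 120
small_spec <- function(seed = 1, noise_sd = 0.5, flatness = 1, ...) {
  phantom_spec(grid_dims = c(9, 4, 9), n_timepoints = 120,
               roi_extent = list(x = 1:4, y = 1:4, z = 1:8),
               n_networks = 3, flatness = flatness,
               noise_sd = noise_sd, seed = seed, ...)
}

phantom_series <- function(ph) {
  roi <- extract_roi_series(ph$bold, ph$roi_mask)
  out <- extract_roi_series(ph$bold, ph$brain_mask & !ph$roi_mask)
  list(roi = roi$series, out = out$series,
       coords = as.matrix(roi$voxels[, c("i", "j", "k")]),
       out_voxels = out$voxels)
}

# brute-force eta-squared via the definitional double loop
eta2_naive <- function(fp) {
  V <- nrow(fp)
  out <- matrix(1, V, V)
  for (a in seq_len(V - 1)) for (b in (a + 1):V) {
    x <- fp[a, ]; y <- fp[b, ]
    m <- (x + y) / 2
    M <- mean(m)
    out[a, b] <- out[b, a] <-
      1 - sum((x - m)^2 + (y - m)^2) / sum((x - M)^2 + (y - M)^2)
  }
  out
}

# dense generalized eigendecomposition oracle for L v = lambda D v
# (plain non-symmetric solve of D^-1 L, independent of the package's
# symmetric-normalization route)
eigenmaps_naive <- function(W, n_maps = 1) {
  diag(W) <- 0
  D <- rowSums(W)
  L <- diag(D) - W
  e <- eigen(diag(1 / D) %*% L)
  ord <- order(Re(e$values))
  lambda <- Re(e$values)[ord]
  vecs <- Re(e$vectors)[, ord, drop = FALSE]
  nontrivial <- which(lambda > 1e-10)
  list(lambda = lambda[nontrivial[seq_len(n_maps)]],
       vectors = vecs[, nontrivial[seq_len(n_maps)], drop = FALSE])
}

# step-down Holm reference: explicit sequential thresholds, no p.adjust
holm_naive <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) reject[ord[i]] <- TRUE else break
  }
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, (m - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(run, 1)
  }
  list(adjusted = adj, rejected = reject)
}

# spearman that restores exact ties broken only by floating-point jitter
spearman_rounded <- function(x, y, digits = 8) {
  stats::cor(round(x, digits), round(y, digits), method = "spearman")
}

# regular 3D coordinate grid for trend-surface tests
grid_coords <- function(nx = 7, ny = 7, nz = 8) {
  as.matrix(expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz)))
}
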