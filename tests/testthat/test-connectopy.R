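test_that("standardization gives unit-variance zero-mean columns and flags
           constant voxels", {
  expect_equal(standardize(matrix(c(1, 2, 3)))[, 1], c(-1, 0, 1))
  set.seed(1)
  X <- matrix(rnorm(40), 10)
  S <- standardize(X)
  expect_equal(colMeans(S), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(S, 2, sd), rep(1, 4), tolerance = 1e-12)
  expect_equal(standardize(S), S, tolerance = 1e-12, ignore_attr = TRUE)
  X[, 3] <- 5
  expect_error(standardize(X), "3")
})

test_that("SVD reduction is lossless for fingerprint geometry", {
  set.seed(2)
  X <- standardize(matrix(rnorm(100 * 500), 100))
  comp <- svd_reduce(X)
  expect_lte(ncol(comp), 99)                      # columns demeaned: C <= T-1
  # rank preservation
  R3 <- matrix(rnorm(30 * 3), 30) %*% matrix(rnorm(3 * 8), 3)
  expect_equal(ncol(svd_reduce(R3)), 3)
  # rotation invariance of the Gram matrix of component time series
  Q <- qr.Q(qr(matrix(rnorm(500 * 500), 500)))
  compQ <- svd_reduce(X %*% Q)
  expect_equal(tcrossprod(comp), tcrossprod(compQ), tolerance = 1e-8)
  # distances among covariance fingerprints are preserved: rows of Z'X vs
  # rows of Z'(U S)
  Z <- matrix(rnorm(100 * 20), 100)
  Fv <- crossprod(Z, X)                 # 20 x 500 voxel-space fingerprints
  Fc <- crossprod(Z, comp)              # 20 x C component-space fingerprints
  expect_equal(as.matrix(dist(Fv)), as.matrix(dist(Fc)), tolerance = 1e-8)
  # and the rotation attribute reconstructs the voxel-space fingerprints
  expect_equal(Fc %*% t(attr(comp, "rotation")), Fv, tolerance = 1e-8)
  expect_error(svd_reduce(matrix(0, 5, 5)), "all-zero")
})

test_that("fingerprints are Pearson correlations with the components", {
  set.seed(3)
  comp <- standardize(matrix(rnorm(50 * 2), 50))
  roi <- cbind(comp[, 1], -comp[, 2], rnorm(50))
  fp <- compute_fingerprints(standardize(roi), comp)
  expect_equal(fp[1, 1], 1)
  expect_equal(fp[2, 2], -1)
  # hand formula on a printed toy: 3 voxels, 2 components, T = 5
  roi5 <- matrix(c(1, 2, 3, 4, 5,
                   2, 1, 4, 3, 5,
                   5, 3, 1, 4, 2), 5)
  comp5 <- matrix(c(1, 1, 2, 3, 5,
                    2, 4, 1, 5, 3), 5)
  hand <- matrix(0, 3, 2)
  for (i in 1:3) for (c in 1:2) {
    x <- roi5[, i]; y <- comp5[, c]
    hand[i, c] <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(compute_fingerprints(roi5, comp5), hand, ignore_attr = TRUE)
  expect_error(compute_fingerprints(roi5, matrix(1, 5, 1)), "zero-variance")
})

test_that("eta-squared matches its definition and worked values", {
  # identical profiles
  expect_equal(eta2_similarity(rbind(c(1, 2, 3), c(1, 2, 3)))[1, 2], 1)
  # the worked pair: a = (1,2), b = (3,0) -> 1 - 4/5
  expect_equal(eta2_similarity(rbind(c(1, 2), c(3, 0)))[1, 2], 0.2)
  # zero-mean opposite profiles are maximally dissimilar
  expect_equal(eta2_similarity(rbind(c(1, -1), c(-1, 1)))[1, 2], 0)
  # vectorized computation equals the definitional double loop
  set.seed(4)
  fp <- matrix(rnorm(15 * 6), 15)
  S <- eta2_similarity(fp)
  expect_equal(S, eta2_naive(fp), tolerance = 1e-12)
  expect_true(isSymmetric(S))
  expect_equal(diag(S), rep(1, 15))
  expect_true(all(S >= 0 & S <= 1))
  expect_error(eta2_similarity(rbind(c(2, 2), c(2, 2))), "denominator")
})

test_that("Laplacian eigenmaps solve the generalized eigenproblem", {
  # 3-node path graph: primary map strictly monotone along the path
  W <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  m <- laplacian_eigenmaps(W, 1)[[1]]
  expect_true(all(diff(m$values) > 0) || all(diff(m$values) < 0))
  # dense-oracle agreement on a random connected graph of 50 nodes
  set.seed(5)
  fp <- matrix(rnorm(50 * 8), 50)
  S <- eta2_similarity(fp)
  maps <- laplacian_eigenmaps(S, 2)
  oracle <- eigenmaps_naive(S, 2)
  for (k in 1:2) {
    expect_equal(maps[[k]]$eigenvalue, oracle$lambda[k], tolerance = 1e-8)
    v <- oracle$vectors[, k]
    v <- (v - min(v)) / (max(v) - min(v))
    if (cor(v, maps[[k]]$values) < 0) v <- 1 - v
    expect_equal(maps[[k]]$values, v, tolerance = 1e-6)
  }
  # explicit residual of the generalized eigenproblem
  W2 <- S; diag(W2) <- 0
  D <- rowSums(W2); L <- diag(D) - W2
  for (k in 1:2) {
    vraw <- maps[[k]]$values  # affine transform of the eigenvector
    # recover unscaled eigenvector direction: L is linear, test on v - c
    resid <- L %*% vraw - maps[[k]]$eigenvalue * D * vraw
    # subtract the component explained by the affine shift of the trivial vec
    shift <- L %*% rep(1, 50) - maps[[k]]$eigenvalue * D * rep(1, 50)
    cc <- sum(resid * shift) / sum(shift^2)
    expect_lt(max(abs(resid - cc * shift)), 1e-6)
  }
  # eigenvalues positive and non-decreasing, trivial vector excluded
  ev <- vapply(maps, `[[`, numeric(1), "eigenvalue")
  expect_true(all(ev > 0))
  expect_true(all(diff(ev) >= 0))
  # identical similarity rows embed to equal values
  fp2 <- rbind(fp, fp[1, ])
  S2 <- eta2_similarity(fp2)
  m2 <- laplacian_eigenmaps(S2, 1)[[1]]
  expect_lt(abs(m2$values[1] - m2$values[51]), 1e-8)
  # disconnected graphs are rejected with component sizes
  Wd <- matrix(0, 4, 4); Wd[1, 2] <- Wd[2, 1] <- 1; Wd[3, 4] <- Wd[4, 3] <- 1
  expect_error(laplacian_eigenmaps(Wd, 1), "disconnected")
})

test_that("noise-free phantom embeds monotonically in the planted gradient", {
  ph <- generate_phantom(small_spec(seed = 6, noise_sd = 0))
  ser <- phantom_series(ph)
  m <- estimate_connectopy(ser$roi, ser$out)[[1]]
  expect_equal(abs(spearman_rounded(m$values, ph$truth$gradient_coord)), 1,
               tolerance = 1e-10)
})

test_that("alignment flips anti-correlated maps and flags poor matches", {
  set.seed(8)
  ref <- runif(40)
  cref <- connectopy(values = (ref - min(ref)) / diff(range(ref)))
  al <- align_connectopy(cref, ref)
  expect_equal(al$reference_r, 1)
  expect_true(al$qc_pass)
  flipped <- connectopy(values = 1 - cref$values)
  al2 <- align_connectopy(flipped, ref)
  expect_equal(al2$reference_r, 1)
  expect_equal(al2$values, cref$values)
  # borderline: post-flip r just below 0.5 fails QC
  set.seed(9)
  repeat {
    noisy <- connectopy(values = runif(40))
    r <- abs(cor(noisy$values, ref))
    if (r > 0.4 && r < 0.5) break
  }
  al3 <- align_connectopy(noisy, ref)
  expect_lt(al3$reference_r, 0.5)
  expect_false(al3$qc_pass)
  expect_error(align_connectopy(cref, rep(1, 40)), "constant")
})

test_that("spatial correlation behaves on identical, negated and null maps", {
  set.seed(10)
  a <- rnorm(100)
  expect_equal(spatial_correlation(a, a), 1)
  expect_equal(spatial_correlation(a, -a), -1)
  mask <- c(rep(TRUE, 50), rep(FALSE, 50))
  expect_equal(spatial_correlation(a, a, mask), 1)
  # Monte-Carlo null: independent maps decorrelated
  rs <- vapply(1:40, function(s) {
    set.seed(s)
    abs(spatial_correlation(rnorm(1000), rnorm(1000)))
  }, numeric(1))
  expect_gte(mean(rs < 0.1), 0.95)
  expect_error(spatial_correlation(a, rep(0, 100)), "constant")
})
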