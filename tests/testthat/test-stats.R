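test_that("Holm correction matches a step-down reference exhaustively", {
  # worked example: thresholds 0.0125, 0.0167, 0.025, 0.05 -> 1 rejection
  h <- holm_correct(c(0.001, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_equal(sum(h$rejected), 1)
  expect_true(h$rejected[1])
  expect_equal(h$adjusted, c(0.004, 0.06, 0.06, 0.06))
  # degenerate families
  expect_equal(holm_correct(rep(1, 5))$adjusted, rep(1, 5))
  expect_equal(sum(holm_correct(rep(1, 5))$rejected), 0)
  h1 <- holm_correct(0.04, alpha = 0.05)
  expect_true(h1$rejected)
  expect_equal(h1$adjusted, 0.04)
  # exhaustive agreement with the sequential reference on all non-empty
  # subsets of a 6-value grid
  grid <- c(0.001, 0.008, 0.02, 0.04, 0.2, 0.6)
  for (mask in 1:63) {
    p <- grid[as.logical(bitwAnd(mask, 2^(0:5)))]
    got <- holm_correct(p, alpha = 0.05)
    ref <- holm_naive(p, alpha = 0.05)
    expect_equal(got$adjusted, ref$adjusted)
    expect_equal(got$rejected, ref$rejected)
  }
  expect_error(holm_correct(numeric(0)), "empty")
  expect_error(holm_correct(c(0.5, 1.2)), "0, 1")
})

test_that("partial correlations residualize both sides on the covariates", {
  set.seed(1)
  n <- 80
  covars <- data.frame(age = rnorm(n, 17, 5),
                       sex = sample(c("M", "F"), n, TRUE),
                       site = sample(paste0("site", 1:3), n, TRUE))
  coeffs <- matrix(rnorm(n * 4), n,
                   dimnames = list(NULL, c("x1", "y1", "z1", "z2")))
  # score equal to one coefficient: partial r = 1 for that term
  res <- associate_coefficients(coeffs, coeffs[, "z1"], covars)
  expect_equal(res$partial_r[res$term == "z1"], 1, tolerance = 1e-10)
  expect_true(res$rejected[res$term == "z1"])
  # score that is pure covariate: all partial r inside the null band
  res2 <- associate_coefficients(coeffs, covars$age + 0.001 * rnorm(n), covars)
  expect_true(all(abs(res2$partial_r) < 2 / sqrt(n)))
  expect_false(any(res2$rejected))
  # with q = 0 covariates it reduces exactly to plain Pearson correlation
  score <- rnorm(n)
  res3 <- associate_coefficients(coeffs, score, NULL)
  expect_equal(res3$partial_r, unname(drop(cor(score, coeffs))),
               tolerance = 1e-12)
  r <- res3$partial_r
  expect_equal(res3$p, 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2),
               tolerance = 1e-12)
  # missing scores are dropped listwise and counted
  score[1:5] <- NA
  res4 <- associate_coefficients(coeffs, score, covars)
  expect_equal(unique(res4$n_dropped), 5)
  expect_equal(unique(res4$n_used), n - 5)
  expect_error(associate_coefficients(coeffs, rep(1, n), covars), "constant")
  expect_error(associate_coefficients(coeffs, rnorm(n),
                                      cbind(covars, age2 = covars$age)),
               "collinear")
})

test_that("association pipeline: family-wise type-I error and power", {
  n <- 60; terms <- 18
  fam_reject <- logical(200)
  power_hit <- logical(200)
  for (s in 1:200) {
    set.seed(s)
    coeffs <- matrix(rnorm(n * terms), n,
                     dimnames = list(NULL, paste0("t", 1:terms)))
    covars <- data.frame(age = rnorm(n), sex = sample(c("M", "F"), n, TRUE))
    # null cohort: score unrelated to every coefficient
    null_score <- rnorm(n) + 0.5 * covars$age
    fam_reject[s] <- any(associate_coefficients(coeffs, null_score,
                                                covars)$rejected)
    # planted partial r = 0.5 on the first term
    z <- rnorm(n)
    coeffs[, 1] <- 0.5 * z + sqrt(1 - 0.25) * rnorm(n)
    power_hit[s] <- associate_coefficients(coeffs, z, covars)$rejected[1]
  }
  mc_sd <- sqrt(0.05 * 0.95 / 200)
  expect_lte(mean(fam_reject), 0.05 + 2 * mc_sd)
  expect_gte(mean(power_hit), 0.8)
})

test_that("group t-tests flag large shifts and nothing under the null", {
  set.seed(3)
  a <- matrix(rnorm(30 * 5), 30, dimnames = list(NULL, paste0("t", 1:5)))
  res0 <- group_ttest(a, a)
  expect_equal(res0$t, rep(0, 5))
  expect_equal(res0$p, rep(1, 5))
  # shift of 5 pooled-sd units: essentially sure rejection, t matches the
  # closed form
  b <- matrix(rnorm(30 * 5), 30) + 5
  res1 <- group_ttest(a, b)
  expect_true(all(res1$rejected))
  t_hand <- (mean(a[, 1]) - mean(b[, 1])) /
    sqrt(((29 * var(a[, 1]) + 29 * var(b[, 1])) / 58) * (2 / 30))
  expect_equal(res1$t[1], t_hand, tolerance = 1e-12)
  # permutation of a null cohort keeps the per-test rejection rate near alpha
  set.seed(4)
  pool <- matrix(rnorm(40 * 3), 40)
  rej <- vapply(1:400, function(i) {
    idx <- sample(40, 20)
    any(group_ttest(pool[idx, , drop = FALSE],
                    pool[-idx, , drop = FALSE])$p <= 0.05)
  }, logical(1))
  # per-family (3 uncorrected tests): expect roughly 1 - 0.95^3, allow MC slack
  expect_lte(mean(rej), (1 - 0.95^3) + 2 * sqrt(0.14 * 0.86 / 400))
  expect_error(group_ttest(a[1, , drop = FALSE], b), "at least 2")
})

test_that("paired t-tests operate on within-subject differences", {
  set.seed(5)
  rest <- matrix(rnorm(20 * 4), 20, dimnames = list(NULL, paste0("t", 1:4)))
  res0 <- paired_ttest(rest, rest)
  expect_equal(res0$t, rep(0, 4))
  # a constant shift with zero difference variance is degenerate
  expect_error(paired_ttest(rest, rest + 0.3), "zero-variance")
  # a real shift in one term only survives Holm there
  task <- rest + matrix(rnorm(20 * 4, sd = 0.2), 20)
  task[, 2] <- task[, 2] + 2
  res1 <- paired_ttest(rest, task)
  expect_true(res1$rejected[2])
  expect_false(any(res1$rejected[-2]))
  # matches t.test on the same differences
  tt <- t.test(rest[, 2] - task[, 2])
  expect_equal(res1$t[2], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res1$p[2], tt$p.value, tolerance = 1e-12)
  expect_error(paired_ttest(rest[1, , drop = FALSE], task[1, , drop = FALSE]),
               "2 pairs")
})

test_that("voxel-wise GLM localizes a planted effect and controls FWE", {
  set.seed(6)
  n <- 40; V <- 150
  g <- runif(V)
  X <- cbind(intercept = 1, diagnosis = rbinom(n, 1, 0.5),
             sex = rbinom(n, 1, 0.5), age = rnorm(n), score = rnorm(n))
  # effect of score only in voxels with g > 0.8
  Y <- matrix(rnorm(n * V, sd = 0.5), n)
  hot <- which(g > 0.8)
  Y[, hot] <- Y[, hot] + X[, "score"] %o% rep(1, length(hot))
  cfg <- stats_config(n_perm = 500, perm_seed = 9)
  res <- glm_voxelwise(Y, X, "score", cfg)
  flagged <- which(res$significant)
  expect_gt(length(flagged), 0)
  expect_gte(mean(flagged %in% hot), 0.8)
  # duplicated column is a rank error
  expect_error(glm_voxelwise(Y, cbind(X, score2 = X[, "score"]), "score"),
               "rank-deficient")
  # null calibration: voxel-wise FWER at alpha over replicate cohorts
  fam <- vapply(1:50, function(s) {
    set.seed(100 + s)
    Y0 <- matrix(rnorm(30 * 60), 30)
    X0 <- cbind(1, rnorm(30))
    any(glm_voxelwise(Y0, X0, 2, stats_config(n_perm = 200,
                                              perm_seed = s))$significant)
  }, logical(1))
  expect_lte(mean(fam), 0.05 + 2 * sqrt(0.05 * 0.95 / 50))
  # Holm variant agrees with parametric p + p.adjust
  resh <- glm_voxelwise(Y, X, "score", method = "holm")
  expect_equal(resh$p_fwe, p.adjust(resh$p, "holm"))
})

test_that("score-conditioned reconstruction tracks the planted coupling", {
  co <- grid_coords(5, 5, 8)
  basis <- build_basis(co, 2)
  set.seed(7)
  n <- 50
  score <- runif(n, 40, 110)
  # coefficients linearly coupled to the score on the z terms
  slope <- c(x1 = 0, y1 = 0, z1 = 0.004, x2 = 0, y2 = 0, z2 = -0.002)
  coeffs <- t(vapply(score, function(s)
    slope * s + rnorm(6, sd = 1e-4), numeric(6)))
  colnames(coeffs) <- basis$terms
  intercepts <- 0.5 + rnorm(n, sd = 1e-4)
  # at the mean score the reconstruction equals the average
  rc <- reconstruct_at_score(coeffs, intercepts, score, mean(score), basis)
  expect_lt(rc$profile$rmse, 1e-5)
  avg_map <- drop(basis$design %*% c(mean(intercepts), colMeans(coeffs)))
  expect_equal(rc$maps[, 1], avg_map, tolerance = 1e-3)
  # three increasing points below the mean: RMSE decreases monotonically
  pts <- seq(min(score), mean(score), length.out = 3)
  rc3 <- reconstruct_at_score(coeffs, intercepts, score, pts, basis)
  expect_true(all(diff(rc3$profile$rmse) < 0))
  # null coupling: profile flat within noise
  coeffs0 <- matrix(rnorm(n * 6, sd = 1e-3), n,
                    dimnames = list(NULL, basis$terms))
  rc0 <- reconstruct_at_score(coeffs0, intercepts, score, pts, basis)
  expect_lt(diff(range(rc0$profile$rmse)), 1e-3)
  expect_warning(
    reconstruct_at_score(coeffs, intercepts, score, 1e4, basis),
    "extrapolat")
})
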