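#' Statistical configuration for the inference layer
#'
#' @param alpha family-wise error rate, default 0.05.
#' @param var_equal pooled-variance (TRUE, default) or Welch t-tests.
#' @param n_perm permutations for voxel-wise max-T inference.
#' @param perm_seed RNG seed for the permutations.
#' @return named list of settings.
#' @export
stats_config <- function(alpha = 0.05, var_equal = TRUE,
                         n_perm = 1000L, perm_seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 1)
  list(alpha = alpha, var_equal = var_equal,
       n_perm = as.integer(n_perm), perm_seed = as.integer(perm_seed))
}

#' Holm step-down multiple-comparison correction
#'
#' Sorts the m p-values ascending, compares p_(i) to alpha/(m - i + 1) and
#' stops at the first failure; the adjusted p-values are the running maximum
#' of (m - i + 1) * p_(i), capped at 1, so that rejection at level alpha is
#' equivalent to adjusted p <= alpha.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param alpha family-wise error rate.
#' @return list with `adjusted` (same order as input) and `rejected`
#'   (logical).
#' @export
holm_correct <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0) stopf("empty p-value list")
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stopf("p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(pvals, method = "holm")
  list(adjusted = adjusted, rejected = adjusted <= alpha)
}

# residualize columns of y on [intercept | covariates]; covariates may be a
# data.frame with factors/characters (expanded to treatment dummies)
residualize <- function(y, covariates = NULL) {
  y <- as.matrix(y)
  if (is.null(covariates) || NCOL(covariates) == 0)
    return(list(resid = sweep(y, 2, colMeans(y)), q = 0L))
  cov_df <- as.data.frame(covariates, stringsAsFactors = TRUE)
  cov_df[] <- lapply(cov_df, function(col) if (is.character(col)) factor(col) else col)
  # constant covariates (e.g. a single-sex subsample) carry no information
  cov_df <- cov_df[, vapply(cov_df, function(col) length(unique(col)) > 1,
                            logical(1)), drop = FALSE]
  if (ncol(cov_df) == 0)
    return(list(resid = sweep(y, 2, colMeans(y)), q = 0L))
  X <- stats::model.matrix(~ ., data = cov_df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stopf("collinear covariates: %s",
          paste(colnames(X)[-qrX$pivot[seq_len(qrX$rank)]], collapse = ", "))
  list(resid = qr.resid(qrX, y), q = ncol(X) - 1L)
}

#' Partial correlations between trend-surface coefficients and a score
#'
#' Per term, both the coefficient and the score are residualized on an
#' intercept plus the covariates by OLS; the partial correlation is the
#' Pearson correlation of the residuals, tested with
#' t = r sqrt((n - 2 - q) / (1 - r^2)) on n - 2 - q degrees of freedom,
#' where q is the number of covariate columns after dummy expansion.
#' Subjects with a missing score or covariate are dropped listwise (count
#' reported in the result). Holm correction is applied across the supplied
#' terms (one family).
#'
#' @param coeffs subjects x terms numeric matrix (column names = term names).
#' @param score per-subject numeric score.
#' @param covariates optional subjects x q data.frame (factors allowed,
#'   e.g. sex and site).
#' @param config a [stats_config()].
#' @return data.frame with term, partial_r, t, df, p, p_holm, rejected,
#'   n_used, n_dropped.
#' @export
associate_coefficients <- function(coeffs, score, covariates = NULL,
                                   config = stats_config()) {
  coeffs <- as.matrix(coeffs)
  n0 <- nrow(coeffs)
  keep <- is.finite(score)
  if (!is.null(covariates))
    keep <- keep & stats::complete.cases(as.data.frame(covariates))
  coeffs <- coeffs[keep, , drop = FALSE]
  score <- score[keep]
  if (!is.null(covariates))
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
  n <- nrow(coeffs)
  if (stats::sd(score) == 0) stopf("constant score")
  rz <- residualize(cbind(score, coeffs), covariates)
  q <- rz$q
  if (n <= q + 3) stopf("n = %d too small for %d covariate columns", n, q)
  score_r <- rz$resid[, 1]
  term_r <- rz$resid[, -1, drop = FALSE]
  df <- n - 2 - q
  r <- drop(stats::cor(score_r, term_r))
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  h <- holm_correct(p, config$alpha)
  data.frame(term = colnames(coeffs) %||% paste0("term", seq_along(r)),
             partial_r = r, t = tstat, df = df, p = p,
             p_holm = h$adjusted, rejected = h$rejected,
             n_used = n, n_dropped = n0 - n,
             row.names = NULL, stringsAsFactors = FALSE)
}

# per-column two-sample t (pooled or Welch), degenerate-safe for t = 0 case
two_sample_t <- function(a, b, var_equal = TRUE) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  delta <- ma - mb
  t <- ifelse(se == 0 & delta == 0, 0, delta / se)
  if (any(se == 0 & delta != 0))
    stopf("degenerate zero-variance term with non-zero group difference")
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Independent-samples t-tests on trend-surface coefficients by group
#'
#' One two-sample t-test per term (pooled variance by default, Welch via
#' `config$var_equal = FALSE`), Holm-corrected across terms.
#'
#' @param coeffs_a,coeffs_b subjects x terms matrices for the two groups.
#' @param config a [stats_config()].
#' @return data.frame with term, t, df, p, p_holm, rejected.
#' @export
group_ttest <- function(coeffs_a, coeffs_b, config = stats_config()) {
  a <- as.matrix(coeffs_a); b <- as.matrix(coeffs_b)
  if (nrow(a) < 2 || nrow(b) < 2) stopf("each group needs at least 2 subjects")
  if (ncol(a) != ncol(b)) stopf("groups have different term layouts")
  res <- two_sample_t(a, b, config$var_equal)
  h <- holm_correct(res$p, config$alpha)
  data.frame(term = colnames(a) %||% paste0("term", seq_along(res$t)),
             t = res$t, df = res$df, p = res$p,
             p_holm = h$adjusted, rejected = h$rejected,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Paired t-tests on coefficients between two conditions
#'
#' One-sample t-test on the within-subject differences per term (e.g. rest
#' minus task), Holm-corrected across terms. Identical conditions give
#' t = 0; a constant non-zero shift with zero difference variance is a
#' degenerate design and raises an error rather than an infinite statistic.
#'
#' @param coeffs_rest,coeffs_task subjects x terms matrices with matching
#'   rows (same subjects, same order; row names checked when present).
#' @param config a [stats_config()].
#' @return data.frame with term, mean_diff, t, df, p, p_holm, rejected.
#' @export
paired_ttest <- function(coeffs_rest, coeffs_task, config = stats_config()) {
  a <- as.matrix(coeffs_rest); b <- as.matrix(coeffs_task)
  if (!all(dim(a) == dim(b))) stopf("condition matrices differ in shape")
  if (nrow(a) < 2) stopf("need at least 2 pairs")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b)))
    stopf("subject sets do not match between conditions")
  d <- a - b
  n <- nrow(d)
  m <- colMeans(d)
  s <- apply(d, 2, stats::sd)
  szero <- s < 1e-12 * pmax(abs(m), 1)
  if (any(szero & abs(m) > 1e-12))
    stopf("zero-variance non-zero difference in term(s): %s",
          paste((colnames(d) %||% seq_len(ncol(d)))[szero & abs(m) > 1e-12],
                collapse = ", "))
  t <- ifelse(szero, 0, m / (s / sqrt(n)))
  p <- 2 * stats::pt(-abs(t), n - 1)
  h <- holm_correct(p, config$alpha)
  data.frame(term = colnames(a) %||% paste0("term", seq_along(t)),
             mean_diff = m, t = t, df = n - 1, p = p,
             p_holm = h$adjusted, rejected = h$rejected,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mass-univariate GLM on raw connectopies with max-T permutation FWE
#'
#' Fits, at every ROI voxel, an OLS model of the connectopy value on the
#' design and tests the contrast column. Family-wise error over voxels is
#' controlled by sign-preserving permutation of the Freedman-Lane type:
#' both the data and the contrast are residualized on the nuisance columns,
#' the contrast residuals are permuted, and the maximum |t| over voxels is
#' recorded per permutation. `method = "holm"` uses parametric p-values
#' with Holm correction instead.
#'
#' @param raw_connectopies subjects x V_roi matrix of connectopy values.
#' @param design subjects x p model matrix (include the intercept).
#' @param contrast name or index of the design column to test.
#' @param config a [stats_config()] (permutation count and seed).
#' @param method "maxT" (default) or "holm".
#' @return data.frame per voxel: t, df, p (parametric), p_fwe, significant.
#' @export
glm_voxelwise <- function(raw_connectopies, design, contrast,
                          config = stats_config(), method = c("maxT", "holm")) {
  method <- match.arg(method)
  Y <- as.matrix(raw_connectopies)
  X <- as.matrix(design)
  n <- nrow(Y)
  if (nrow(X) != n) stopf("design has %d rows, data has %d", nrow(X), n)
  if (n < ncol(X) + 2) stopf("need at least p + 2 subjects")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stopf("rank-deficient design; check column(s): %s",
          paste(colnames(X)[-qrX$pivot[seq_len(qrX$rank)]], collapse = ", "))
  ci <- if (is.character(contrast)) match(contrast, colnames(X)) else as.integer(contrast)
  if (is.na(ci) || ci < 1 || ci > ncol(X)) stopf("contrast column not found")
  Z <- X[, -ci, drop = FALSE]
  qrZ <- qr(Z)
  xr <- qr.resid(qrZ, X[, ci])
  Yr <- qr.resid(qrZ, Y)
  df <- n - ncol(X)
  t_from <- function(xv) {
    xs <- xv / sqrt(sum(xv^2))
    r <- drop(crossprod(xs, Yr)) / sqrt(colSums(Yr^2))
    r <- pmin(pmax(r, -1), 1)
    r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  }
  tobs <- t_from(xr)
  p <- 2 * stats::pt(-abs(tobs), df)
  if (method == "holm") {
    h <- holm_correct(p, config$alpha)
    p_fwe <- h$adjusted; sig <- h$rejected
  } else {
    maxT <- with_seed(config$perm_seed, {
      vapply(seq_len(config$n_perm),
             function(b) max(abs(t_from(sample(xr)))), numeric(1))
    })
    p_fwe <- vapply(abs(tobs), function(t0) (1 + sum(maxT >= t0)) /
                      (config$n_perm + 1), numeric(1))
    sig <- p_fwe <= config$alpha
  }
  data.frame(voxel = seq_along(tobs), t = tobs, df = df, p = p,
             p_fwe = p_fwe, significant = sig, row.names = NULL)
}

#' Score-conditioned reconstruction of the connectopy
#'
#' Regresses every trend-surface coefficient (and the intercept) on the
#' behavioural score across subjects, predicts the full coefficient vector
#' at chosen score points, reconstructs the corresponding maps, and reports
#' the RMSE between each predicted coefficient vector and the cohort-average
#' coefficients, restricted to the configured axis terms (default z, the
#' gradient direction). A decreasing RMSE across increasing score points
#' means the topography approaches the average (sharper, less flat) shape
#' as the score rises.
#'
#' @param coeffs subjects x terms matrix of fitted coefficients.
#' @param intercepts per-subject fitted intercepts.
#' @param score per-subject score the coefficients are conditioned on.
#' @param score_points score values at which to reconstruct (points far
#'   outside the observed range trigger an extrapolation warning).
#' @param basis the common [build_basis()] the coefficients live in.
#' @param average_model optional `tsm_model` to compare against; by default
#'   the cohort-average coefficient vector.
#' @param axis_filter axes entering the RMSE (default "z").
#' @return list with `profile` (data.frame score_point, rmse) and `maps`
#'   (V_roi x length(score_points) reconstructed maps).
#' @export
reconstruct_at_score <- function(coeffs, intercepts, score, score_points,
                                 basis, average_model = NULL,
                                 axis_filter = "z") {
  coeffs <- as.matrix(coeffs)
  stopifnot(inherits(basis, "tsm_basis"),
            length(intercepts) == nrow(coeffs), length(score) == nrow(coeffs))
  rng <- range(score)
  span <- diff(rng)
  if (any(score_points < rng[1] - 0.5 * span | score_points > rng[2] + 0.5 * span))
    warnf("score point(s) far outside the observed range; extrapolating")
  # per-term OLS of coefficient on score: predictions pass through the means
  X <- cbind(1, score)
  B <- solve(crossprod(X), crossprod(X, cbind(intercepts, coeffs)))
  avg_coef <- if (is.null(average_model)) colMeans(coeffs) else average_model$coefficients
  Xp <- cbind(1, score_points)
  pred <- Xp %*% B                       # points x (1 + terms)
  maps <- sapply(seq_along(score_points), function(i)
    drop(basis$design %*% pred[i, ]))
  rmse <- vapply(seq_along(score_points), function(i)
    rmse_coefficients(stats::setNames(pred[i, -1], basis$terms),
                      avg_coef, axis_filter = axis_filter), numeric(1))
  list(profile = data.frame(score_point = score_points, rmse = rmse),
       maps = maps)
}
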