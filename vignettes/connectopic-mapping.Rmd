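---
title: "Connectopic mapping with trend-surface summaries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectopic mapping with trend-surface summaries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Classical region-of-interest analyses of functional MRI treat a cortical
region as a homogeneous patch: one time series, one connectivity profile.
Many primary cortices are not like that. Primary somatosensory cortex, for
example, is somatotopically organized — adjacent body parts map to adjacent
cortex — and its connectivity to the rest of the brain changes *gradually*
across the region rather than in parcel-like steps. Connectopic mapping
estimates this gradual change directly: it assigns every ROI voxel a
coordinate on a smooth spatial map (a "connectopy") such that voxels with
similar whole-brain connectivity profiles receive similar values. The map's
dominant axis can then be summarized with a handful of polynomial
coefficients, compared between conditions (rest vs. task), and related to
behavioural scores across individuals.

This package implements that full chain in R, together with a synthetic
phantom generator that plants a known gradient and a known
gradient-flatness-to-behaviour coupling, so every stage can be validated
against ground truth. That matters here more than usually: the cohorts this
method was developed for are access-controlled, so the package's
correctness argument rests entirely on recovering planted structure.

## The estimation chain

For one subject, one ROI:

1. **Extraction** (`extract_roi_series()`): in-mask time series in a
   canonical voxel order (ascending flat index, x fastest), so results never
   depend on file layout.
2. **Preprocessing** (`preprocess_series()`): one OLS projection removes the
   intercept, any confound time series (white matter, CSF), and a
   discrete-cosine drift basis covering all frequencies below the high-pass
   cutoff (default 0.01 Hz). A single concatenated design is used rather
   than chaining separate regressions: sequential projections onto
   non-orthogonal bases are *not* equivalent to the joint projection, and
   the joint fit is the statistically correct one.
3. **Standardization** (`standardize()`): each voxel to mean 0, unit
   variance. A zero-variance voxel is an error that feeds the
   "insufficient ROI variance" exclusion rule.
4. **SVD reduction** (`svd_reduce()`): the out-of-ROI time-by-voxel matrix
   X is replaced by U·S from its economy SVD (components with singular
   value above 1e-10 of the largest). Everything downstream depends on the
   out-of-ROI data only through inner products with ROI voxels, and those
   are exactly preserved; the kept right singular vectors are returned so
   the voxel-space fingerprints can be reconstructed, which is what the
   test suite does to verify losslessness.
5. **Fingerprints** (`compute_fingerprints()`): Pearson correlation of each
   ROI voxel with each component time series.
6. **Similarity** (`eta2_similarity()`): the eta-squared coefficient between
   every pair of fingerprint rows — one minus within-pair variance over
   total variance; 1 for identical profiles, 0 for maximally dissimilar
   ones.
7. **Spectral embedding** (`laplacian_eigenmaps()`): the similarity matrix
   with zeroed diagonal is taken as a dense weighted graph W; connectivity
   is checked; the generalized eigenproblem L v = λ D v (L = D − W,
   D = diag of row sums) is solved through the symmetrically normalized
   Laplacian. Eigenvalues are sorted ascending, the trivial constant
   eigenvector (λ ≈ 0) is discarded, and the next map(s) are min–max
   scaled to [0, 1]. The first non-trivial eigenvector — the Fiedler
   vector of the similarity graph — is the primary connectopy.
8. **Alignment and QC** (`align_connectopy()`): eigenvector sign is
   arbitrary, so maps anti-correlated with a reference are flipped
   (v → 1 − v). The post-flip correlation doubles as a quality score;
   maps below r = 0.5 fail QC, mirroring reference-based exclusion in
   practice. On phantoms the planted gradient serves as the reference.
9. **Trend-surface model** (`build_basis()`, `fit_tsm()`,
   `select_order()`): the map is regressed on per-axis monomials of
   standardized voxel coordinates — columns (1, x, y, z, x², y², z², …),
   3k terms at order k, 18 at order 6, no cross-terms. The order is chosen
   by the global BIC minimum over 1..max_order, with
   BIC = n·ln(RSS/n) + p·ln(n) and p counting intercept, coefficients and
   noise variance; the full BIC/EV table is returned so the
   parsimony-versus-fit trade-off is auditable.
10. **Projection** (`dual_regression()`): stage 1 regresses each time
    frame's ROI values on the demeaned spatial map (plus intercept) to get
    a subject time course, which is variance-normalized; stage 2 regresses
    every brain voxel's series on that time course (plus intercept) to get
    a whole-brain coefficient image. Normalization makes the projection
    invariant to the map's scale.

`run_pipeline()` chains 1–10 per subject, isolates per-subject failures,
fixes a common trend-surface order across subjects (given, or the modal
BIC choice), and feeds the coefficient matrix into the inference layer.

## The inference layer

- `associate_coefficients()`: per coefficient, both the coefficient and the
  behavioural score are residualized on an intercept plus covariates (age,
  sex, site, IQ — factors are dummy-coded); the partial correlation of the
  residuals is tested with t = r·sqrt((n−2−q)/(1−r²)) on n−2−q degrees of
  freedom, and Holm's step-down correction is applied across the terms of
  one family. Missing scores are dropped listwise and counted. With no
  covariates this reduces exactly to plain Pearson correlation.
- `group_ttest()` / `paired_ttest()`: independent (pooled variance by
  default, Welch optional) and paired t-tests per term, Holm-corrected.
  Identical inputs give t = 0 rather than an error; a constant non-zero
  paired shift with zero difference variance is reported as a degenerate
  design instead of an infinite statistic.
- `glm_voxelwise()`: mass-univariate OLS on the raw (un-summarized)
  connectopy values, testing one contrast column. Family-wise error over
  voxels is controlled by max-T permutation of the nuisance-residualized
  contrast against nuisance-residualized data; spatial correlation between
  voxels makes Holm conservative here, so permutation is the default and
  Holm the option.
- `reconstruct_at_score()`: every coefficient (and the intercept) is
  regressed on the score; the full coefficient vector is predicted at
  chosen score points and the corresponding maps reconstructed. The RMSE
  between each predicted coefficient vector and the cohort average —
  restricted to the gradient axis's terms (default z) — profiles how the
  topography approaches the average shape as the score rises. Because the
  per-term model is linear, the prediction at the mean score *is* the
  cohort average and its RMSE is zero; a planted positive coupling
  therefore yields a strictly decreasing RMSE across increasing score
  points chosen below the mean, while a null coupling leaves only
  sampling noise in the slopes.

## The phantom generator

`generate_phantom()` builds the smallest 4D volume that exercises the whole
chain. K "network" time courses τ_k are white noise smoothed with a
3-TR moving average (circular, then standardized) — band-limited like BOLD,
with no haemodynamic model, since only the correlation structure matters
downstream. The out-of-ROI brain is K contiguous slabs, one per network
(voxel in slab k = τ_k + noise). Each ROI voxel mixes the networks with
Gaussian bump weights w_k(g) centred at K equally spaced points on [0, 1],
evaluated at the voxel's planted gradient coordinate

  g = 0.5 + θ·(p − 0.5),

where p is the normalized position along the gradient axis and
θ ∈ (0, 1] is the subject's *flatness*: θ = 1 gives the full topography,
smaller θ compresses the gradient towards its midpoint so the voxels'
connectivity profiles become more alike — the phantom's rendering of
reduced functional differentiation.

Two generator choices deserve comment:

- **Bump width.** The bump SD is 1/K. Substantially narrower bumps (e.g.
  1/(2K)) make the fingerprints nearly one-hot: distant positions on the
  gradient all look equally dissimilar, the similarity matrix loses its
  long-range ordering, and no spectral embedding — ours or an independent
  one — can order the networks along the axis. With SD = 1/K adjacent
  bumps overlap strongly and the fingerprint moves smoothly along a curve,
  which is the regime the method is designed for and the regime real
  somatotopic gradients occupy.
- **Default conditions.** The default spec (ROI 6×6×10 voxels, K = 4
  networks, T = 200 volumes, noise SD 0.5, θ = 1) is the fixed study
  condition for all recovery claims: at these settings the primary
  connectopy reaches |Spearman ρ| ≥ 0.9 against the planted gradient in
  over 95% of seeds, and a simulated cohort's flatness values are
  recoverable from the fitted linear-z coefficients (Spearman > 0.8).

`generate_cohort()` draws per-subject flatness uniformly from [0.3, 1]
(cases shifted down by `group_flatness_shift`), couples a behavioural score
to it linearly (score = intercept + b·θ + noise), adds age/sex/site
covariates loosely modelled on a large multi-site developmental cohort
(age 17 ± 5 years, 68% male, 4 sites), and derives one RNG stream per
subject from (seed, subject index) so subjects are statistically decoupled
and any subset is reproducible.

### What the phantom does not emulate

No haemodynamic response, no task design, no motion or physiological
artifacts, no spatial autocorrelation of the noise, no registration error,
and a brain that consists only of the ROI and the network slabs. Passing
tests therefore demonstrate that the *estimator chain* is correct and
well-calibrated under known structure — not that real acquisitions meet
the chain's assumptions. The θ parameterization of flatness is itself an
assumption: no quantitative description exists of how gradient flattening
manifests in real somatosensory data, so the phantom's coupling should be
read as a mechanism for validation, not as a biophysical claim.

## Numerical choices

- Eigenproblem: solved via the symmetric normalization
  D^{-1/2} L D^{-1/2} and a dense symmetric eigendecomposition; residuals
  ‖Lv − λDv‖∞ are checked against 1e-8 at solve time. Near-degenerate
  leading eigenvalues (relative gap < 1e-6) raise a warning and flag the
  map, since the primary/secondary rotation is then unstable.
- Trivial-eigenvector detection: λ < 1e-10 together with a coefficient of
  variation < 1e-6.
- BIC at near-exact fits: RSS is floored at 1e-12 of the total sum of
  squares inside the BIC formula only, so that exactly fitting nested
  models tie on the likelihood term and the parsimony penalty selects the
  lowest order instead of floating-point noise in a ~1e-30 residual.
- Ill-conditioned trend-surface designs (condition number above 1e10, as
  can happen at high order on small ROIs) fall back to a ridge solve with
  λ = 1e-8; exact rank deficiency is an error, and orders that are
  infeasible for a given ROI geometry (an axis with fewer distinct voxel
  levels than the polynomial degree) are reported as NA by
  `select_order()` and skipped.
- Exclusion thresholds (mean FD > 0.7 mm, max FD > 3.8 mm, ROI variance
  below 1e-6, reference correlation below 0.5) are all strict
  inequalities: a subject sitting exactly at a threshold is retained.
  Framewise displacement uses the Power formulation with a configurable
  50 mm head radius and configurable column ordering, since conventions
  differ between realignment tools.
- Dual-regression time courses that are numerically zero (map orthogonal
  to the data) are kept at zero rather than variance-normalized.

## Problem sizes used by the test suite and acceptance script

Gradient recovery is measured over 20 phantom seeds at the default study
conditions; BIC order recovery over 50 noisy surfaces (noise SD 0.01);
association calibration and power over 200 simulated cohorts of n = 60
with 18 terms; the score-conditioned RMSE profile on one cohort of n = 40
phantoms; the eigen-solver oracle on graphs of up to 50 nodes; SVD
losslessness on a phantom with 144 out-of-ROI voxels. These sizes were
chosen as the smallest instances that still give each Monte-Carlo estimate
a comfortable margin around its threshold.

## Known limitations

- Volumetric only; no surface (vertex-wise) variant.
- The dense similarity graph costs O(V²) memory in ROI voxels; the
  symmetrized k-nearest-neighbour sparsification (`knn` argument) is
  available for large ROIs but off by default, since the analyses this
  package targets use ROIs of a few hundred voxels.
- The per-term linear model behind `reconstruct_at_score()` is one
  faithful reading of score-conditioned reconstruction; other readings
  (e.g. joint multivariate regression of all coefficients) would differ
  away from the mean score.
- Holm's family is, by default, the set of terms within one score and
  condition; correcting across scores or hemispheres as well is a
  configuration choice, not a default.
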