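---
title: "Methods: normative modeling of striatal glucose metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative modeling of striatal glucose metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatnorm)
```

# The problem

FDG-PET measures regional glucose consumption, and caudate metabolism
declines with age while putamen metabolism barely moves. A normative model
turns that population trend into a reference chart: it maps age to the full
distribution of caudate uptake in healthy subjects, so an individual can be
scored by how far they sit from the expectation for their age (a deviation
Z-score), the way pediatric growth charts score height. This package
implements the whole workflow — intensity normalization, ROI and voxel-wise
age statistics, and the normative model itself — together with a calibrated
synthetic cohort generator so every stage is testable end to end without
imaging data.

# The normative model

The model is Bayesian linear regression with a warped likelihood. Writing
`y` for regional uptake and `x` for age:

1. **Standardization.** `y` is centered and scaled by its training mean and
   SD. Without this the warp parameters are poorly conditioned: on SUV-scale
   data (values near 1, SD near 0.07) the evidence can drive `(a, b)` to
   degenerate corners because `asinh` is nearly linear over such a narrow
   range. Standardizing first is common practice in normative modeling and
   costs nothing — it composes with the warp into the model's
   response-to-latent map.
2. **Warp.** The standardized response is mapped to a Gaussian latent
   variable by the sinh-arcsinh (SHASH) transform
   `z = sinh(b·asinh(y_s) − a)`, with skew `a` and tail weight `b > 0`;
   `(a, b) = (0, 1)` is the identity. The warp direction is
   observed-to-latent, with the Jacobian `Σ log dz/dy` added to the model
   evidence.
3. **Basis.** The age effect is a cubic B-spline with five evenly spaced
   interior knots over the training age range and clamped (4-fold repeated)
   boundary knots — nine spline columns forming a partition of unity — plus
   an appended intercept. The intercept is redundant with the partition of
   unity; the Bayesian posterior tolerates the collinearity because the
   prior precision `α > 0` regularizes it. All posterior algebra runs
   through an eigendecomposition of `ΦᵀΦ`, which stays stable for any
   `α, β > 0` regardless of that collinearity.
4. **Posterior.** For fixed hyperparameters, `S_w = (αI + βΦᵀΦ)⁻¹` and
   `m_w = β S_w Φᵀ z` in closed form. The latent predictive at a new age is
   `m* = φ(x)ᵀm_w`, `s*² = 1/β + φ(x)ᵀS_wφ(x)`.
5. **Hyperparameters.** `(log α, log β, a, log b)` minimize the negative
   log marginal likelihood of the warped model: the standard Gaussian-BLR
   evidence of `z` minus the Jacobian term. Optimization is Nelder-Mead
   (relative tolerance 1e-8, up to 1000 iterations) from six fixed start
   points: a data-driven initialization (`β` from the residual variance of
   a ridge pilot fit, `α = 1`, identity warp) plus perturbations of the
   warp parameters and a low-`α` start. Fixed starts rather than random
   restarts make fits bit-reproducible without seed plumbing; the fitted
   evidence never exceeds its value at the identity-warp initialization,
   and the suite asserts this. When only one hyperparameter is free the
   search uses Brent's method instead.

From the fit: centile curves `y_q(x) = γ⁻¹(m* + Φ⁻¹(q)·s*)` (monotone in
`q` because the warp inverse is strictly increasing), deviation scores
`Z = (γ(y) − m*)/s*`, and extreme flags at strictly `Z > 2` or `Z < −2`.
Model generalizability is scored by the explained variance
`EV = 1 − Var(y − ŷ)/Var(y)` on a held-out half, with the point prediction
`ŷ` taken as the back-transformed predictive **median** `γ⁻¹(m*)`: the
predictive mean has no closed form under warping, and the median maps
through the monotone warp exactly. EV is computed in response units, not in
the warped space, since that is the scale on which predictions are used.

## Train/test split

The cohort is halved with sex and age balanced: within each sex, subjects
are sorted by age and assigned alternately to the halves. The alternation
phase is seeded, and phases of odd-sized sex strata are paired off so the
halves come out exactly n/2 each (58/58 for the default cohort). This is
one simple scheme that guarantees per-sex counts differ by at most one and
train/test mean ages differ by well under two years.

# The synthetic cohort generator

The generator is the package's stand-in for the study population, and its
defaults are the study conditions, not tuning knobs.

- **Demographics.** 116 subjects — 77 male, 39 female, ages 20–81 — with
  fixed decade-bin counts (e.g. 14 males aged 31–40). Ages are uniform
  within bins: the weakest assumption consistent with binned counts; the
  true within-bin distribution is unknown.
- **Regional uptake.** Each region follows
  `SUV = baseline + slope·(age−50) + curvature·(age−50)² + ε`, with
  SHASH-distributed ε (location 0). The caudate has negative slope and
  negative curvature (decline accelerating in older age) and mildly
  right-skewed noise (`a = 0.3, b = 1`); the putamen has a weak positive
  purely linear trend with Gaussian noise, and correspondingly no
  out-of-sample predictive power.
- **Calibration.** The region-level Pearson correlations with age
  (−0.55/−0.56 caudate left/right, +0.16/+0.21 putamen) and the normative
  model's test-half explained variance (0.36/0.34 caudate; ≤ 0 putamen)
  jointly constrain how nonlinear the caudate trend must be: with total
  uptake variance fixed at 0.01 (SD 0.1 in normalized units, a realistic
  between-subject spread), the correlation pins `Cov(age, f)` and a
  candidate true-curve variance fraction `R²` pins `Var(f)`, leaving a
  two-equation system for (slope, curvature) solved exactly from the
  moments of the binned-uniform age law. `R²` itself was then searched on
  a grid against the 200-replicate mean test EV of the actual fit
  (finite-sample fitting eats a few EV points relative to the true-curve
  fraction), landing at 0.429 (left) and 0.410 (right). The putamen needs
  no search: its slope follows from the target correlation directly. The
  resulting defaults are frozen in `roi_generator_params()`.
- **Volumes.** PET-like volumes are small (40×48×40, ≈77k voxels): boxes
  for the four striatal regions mirrored across the mid-sagittal plane
  inside an ellipsoidal parenchyma, each region's voxels scattered about
  the subject's ROI value, the whole volume multiplied by a per-subject
  log-normal global intensity factor. They exercise the normalization,
  extraction and voxel-wise logic at desk scale; they do not emulate
  scanner point-spread, attenuation or partial-volume effects, so passing
  tests say nothing about image realism — only about the analysis logic.

What the synthetic data do **not** carry over from real data: spatial
autocorrelation beyond region membership, site or scanner batch effects,
sex differences in the age trend (both sexes share one generating process),
and any true individual-level pathology behind extreme deviations.

# Preprocessing choices

- The intensity-normalization band `[0.4·max, 0.9·max]` is inclusive on
  both ends, and the band mask is computed on the whole input volume rather
  than a prior brain mask: with background near zero, background voxels
  fall below the band anyway, and this keeps the rule free of an extra
  mask parameter. A constant volume has an empty band (the maximum itself
  exceeds 0.9·max) and errors explicitly.
- The "global" nuisance covariate of the voxel-wise model is the mean over
  the nonzero-label atlas mask — deterministic and testable, rather than an
  iterative heuristic global estimator.
- Voxel indices are 0-based in reports and converted to mm through the
  affine only at reporting time.

# Voxel-wise inference

Family-wise error is controlled by the permutation distribution of the
maximum |t| over the mask rather than random-field theory: RFT's smoothness
estimation is out of proportion for desk-scale grids, while the max-statistic
permutation test is exact under exchangeability. Nuisance covariates are
handled by the Freedman-Lane scheme (permute residuals of the reduced model,
add back the nuisance fit, refit the full model). Clusters use
26-connectivity with a 50-voxel extent threshold by default; the height
threshold is the empirical (1−α) quantile of the max-|t| null, two-tailed by
construction. The error-control simulation in the suite runs at α = 0.05,
where 200 replicates give informative binomial bounds.

# Numerical notes and degenerate inputs

- Posterior algebra via eigendecomposition of `ΦᵀΦ` (eigenvalues clamped at
  zero); no Cholesky of near-singular matrices.
- `optim` failures at a start point are caught and the start skipped; an
  error is raised only if every start fails or the evidence is non-finite
  at the initialization.
- Out-of-range prediction ages are clamped to the training range with a
  warning (the boundary basis values are held).
- Ties in age are harmless; fitting requires at least two distinct ages
  and at least one more observation than basis columns.
- Explained variance of an (all but) constant prediction is 0 only up to
  floating-point noise — the putamen's median EV across replicates is
  ~1e-10, which the tests treat as zero.

# Problem sizes

The replicate analyses in the tests and the acceptance script use 200
synthetic cohorts of 116 subjects (the study's sampling design), the
error-control simulation uses 200 null datasets of 12 subjects with 120
permutations at a 144-voxel mask, and the voxel-wise qualitative check uses
one 116-subject cohort at the default 40×48×40 grid with 200 permutations.
These sizes put Monte-Carlo error comfortably inside the tolerances asserted
while keeping the whole suite at desk scale.

# Known limitations

- Sex is balanced in the split but not a model covariate; the normative
  model is age-only.
- The SHASH generator applies the warp to residuals while the model warps
  the (standardized) response; the families overlap but are not identical,
  which is also true of real data and is absorbed by calibration.
- Real-data quantities that depend on the full imaging pipeline (exact
  peak coordinates, T-values, per-study Z ranges) are out of scope for the
  synthetic workflow.
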