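---
title: "Methods: T2* relaxometry, placental morphometrics and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: T2* relaxometry, placental morphometrics and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placentaflow)
```

## Scientific background

Placental T2* measured by multi-echo gradient-echo MRI shortens as
deoxyhemoglobin accumulates, making it a non-invasive marker of
placental oxygenation. In pregnancies complicated by fetal congenital
heart disease (CHD), reduced placental T2* — after adjusting for
gestational age (GA), since T2* falls naturally over gestation — is
evidence of impaired placental function, and its relationship with
fetal-brain T2* speaks to whether the fetal brain shares that
oxygenation deficit. This package implements that full measurement and
inference chain and, because such clinical data are not publicly
available, ships generators that produce synthetic data with known
ground truth for every quantity the pipeline estimates.

## Signal model and fitting

Each voxel's multi-echo signal is modelled as mono-exponential decay,

$$S(TE) = S_0 \, e^{-TE/T_2^*},$$

sampled at the five echo times `r paste(echo_times(), collapse = ", ")`
msec on a 2.5 mm isotropic grid (both defaults; arbitrary echoes and
spacings are supported).

Fitting is two-stage:

1. **Log-linear initializer.** Ordinary least squares of
   $\ln S$ on $TE$ gives starting values for $(S_0, R_2^* = 1/T_2^*)$.
   Voxels with non-positive signals at any echo, or a non-positive
   initial decay rate, cannot be initialized and are flagged
   non-converged rather than guessed at.
2. **Levenberg–Marquardt refinement.** A vectorized LM solver refines
   $(S_0, R_2^*)$ against the untransformed signals (the log transform
   distorts the noise weighting). Steps are accepted only when they
   reduce the residual sum of squares, so the refined fit is never
   worse than its initializer. $T_2^*$ is constrained to
   (0.01, 1000] msec; the 1000 msec cap marks the model's physical
   ceiling for tissue.

ROI summaries use `mean_t2star()`, which averages valid in-mask voxels
strictly below a 500 msec reporting threshold: free fluid (amniotic
fluid, blood pools) has much longer T2* than tissue, and the threshold
keeps such voxels from inflating tissue means.

Against a noiseless phantom the fit inverts the forward model to
machine precision. At first-echo SNR 20 the median voxelwise relative
error is about 6 % — this is the information limit of the five-echo
protocol itself (an independent reference implementation,
`minpack.lm::nlsLM`, agrees with our solver to $3\times10^{-6}$ on
identical data), not a solver artifact.

## Morphometrics

All shape metrics derive from a Euclidean distance transform (EDT)
computed by the exact separable lower-envelope algorithm, weighted per
axis by the voxel spacing so distances are in millimeters on
anisotropic grids. Distances are to the nearest background voxel
centre; an isolated foreground voxel is one spacing from background.

- **Volume** is the foreground count times the voxel volume.
- **Morphology score** is the mean plus the (population) SD of in-mask
  distances. It rises when the organ is bulkier (deeper interior) and
  when its thickness is less uniform (wider distance spread). We use
  the population SD because the score summarizes the realized mask,
  not a sample from a larger population. Note the score is mm-valued
  even though it is conventionally reported unitless; we document the
  unit rather than hide it.
- **Maximum thickness** is twice the largest distance — the diameter
  of the largest inscribed sphere, a lower bound on (and in slab-like
  geometry equal to) the anatomical thickness.

The EDT is verified voxel-for-voxel against an $O(n^2)$ brute-force
nearest-background search, and the metrics against analytic values for
digital balls and slabs.

## Texture

Placental heterogeneity is summarized by the Haralick correlation of a
grey-level co-occurrence matrix (GLCM):

1. In-mask T2* values are quantized to 32 levels between the 1st and
   99th in-mask percentiles (percentile anchoring makes the metric
   invariant to affine intensity rescaling); values above the 500 msec
   threshold are excluded before binning.
2. Co-occurrences are accumulated over the three axis-aligned unit
   offsets and their negations (symmetric GLCM), for in-mask pairs
   only.
3. The Haralick correlation
   $(\sum_{ij} p_{ij}\, i j - \mu^2)/\sigma^2$ is returned; a constant
   image has $\sigma^2 = 0$ and yields `NA`.

Values near 1 indicate spatially smooth fields; white noise scores
near 0; a two-level checkerboard attains −1. Lower values mean more
heterogeneous tissue, and the generator's field-correlation-length dial
reproduces that direction monotonically.

## Cohort statistics

The statistical plan mirrors standard practice for GA-confounded
cohorts:

- **Demographics**: Mann–Whitney tests on GA and maternal age (exact
  when combined $n \le 12$ without ties, normal approximation with tie
  correction otherwise).
- **GA correlations**: midrank Spearman $\rho$ with a $t$
  approximation on $n-2$ df, pooled and per group.
- **Group comparisons**: ANCOVA (`y ~ group + ga_weeks`) for the
  T2*-type metrics and volume, with estimated marginal means computed
  at the pooled GA mean directly from the coefficient vector and
  covariance matrix (cross-checked against **emmeans**); one-way ANOVA
  for texture, thickness and morphology. Benjamini–Hochberg FDR is
  applied within this six-test family.
- **Partial correlations**: GA-partialled Spearman correlations
  (rank-residualization; $n-3$ df), pooled and per group, for
  brain-vs-placenta T2* and texture-vs-placental-T2*, each with a
  group-interaction slope test; FDR within the partial-correlation
  family.
- **Summaries**: a Shapiro–Wilk gate ($\alpha = 0.05$) selects
  mean ± SD or median/IQR per metric per group.

All non-trivial primitives are tested against oracles: Spearman p
against the exact permutation null at $n=8$, partial Spearman against
its closed form, BH against the definitional step-up, ANCOVA against
generative ground truth under deliberate confounding. A 400-replicate
null-cohort study confirms every test's type-I error stays at the
nominal 5 % level.

## Synthetic generators

Generator defaults are the package's study conditions, fixed up front:

- **Phantom** (`phantom_spec()`): a 64³ grid of 2.5 mm voxels holding a
  placental disc (radius 45 mm, base thickness 34 mm) whose surfaces
  carry a smooth half-cosine dome of amplitude 4 mm and half-width
  40 mm at a seed-random position — amplitude 0 is a rotationally
  symmetric disc, and larger amplitudes make the organ bulkier and
  less uniform, which strictly raises the morphology score (amplitude
  steps must exceed the 2.5 mm voxel quantum to register on the
  discretized surface). A fetal-brain ellipsoid (30/25/22 mm) sits
  above it. T2* fields are smoothed Gaussian noise renormalized to the
  target mean/SD (placenta 90 ± 15 msec, correlation length 7.5 mm;
  brain 210 ± 8 msec), clipped to (5, 450); background fluid is
  600 msec, above the reporting threshold by construction. Noise is
  zero-truncated Gaussian with SD set so the mean in-placenta
  first-echo signal has SNR 20.
- **Cohort** (`cohort_spec()`): 30 controls and 51 CHD subjects with a
  shared latent oxygenation factor driving correlated placental and
  brain T2*, GA slopes, CHD offsets, and the study's confounding
  structure (controls scanned at later GA than CHD). `"table"` mode
  draws metric values directly; `"image"` mode renders each subject as
  a phantom and pushes it through the full imaging pipeline, so the
  measurement chain itself can be validated against the generative
  parameters. `null_cohort_spec()` zeroes every effect for calibration
  studies.

Limits: phantoms are geometric idealizations (no motion, bias fields,
Rician noise floor or partial-volume modelling), and image-mode
cohorts vary organ means but not per-subject geometry, so morphology
varies only through dome placement.

## Reproducibility

Every stochastic routine takes an explicit seed and restores the
caller's RNG state. The `analysis/` scripts rerun the package's own
study end to end, and `scripts/acceptance.R --seed <int> --out <path>`
recomputes the verification quantities against the installed package.
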