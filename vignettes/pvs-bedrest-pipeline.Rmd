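---
title: "MV-PVS morphometry, DTI-ALPS and longitudinal bed-rest analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MV-PVS morphometry, DTI-ALPS and longitudinal bed-rest analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsbedrest)
```

## What this package computes

Head-down-tilt bed rest (HDBR) is the standard ground analog of spaceflight:
it produces the headward fluid shifts and body unloading seen in
microgravity, optionally combined with mildly elevated ambient CO~2~ to
mimic space-station air. A fraction of participants develop signs of
spaceflight-associated neuro-ocular syndrome (SANS) — optic disc edema,
choroidal folds, globe flattening, or a hyperopic refractive shift greater
than 0.75 D. This package implements the full computational chain used to
ask whether MRI-visible perivascular spaces (MV-PVS) and a diffusivity
index along the perivascular space (DTI-ALPS) respond to bed rest, and
whether that response differs by SANS status:

1. **Detection** of MV-PVS as locally hypointense voxel clusters in
   white matter on T1-weighted images.
2. **Morphometry**: per-cluster volume, length and width; per-subject
   summaries normalised to white-matter volume.
3. **DTI-ALPS**: diffusion tensor fitting and a ratio of diffusivities in
   projection- and association-fiber ROIs.
4. **Longitudinal statistics**: per-metric group-by-time linear models
   over the two bed-rest campaigns, stratified by SANS status.
5. **Synthetic data**: seed-reproducible generators for all three input
   kinds, so every stage is verifiable end to end without access to the
   (restricted) cohort data.

The pipeline consumes already skull-stripped, tissue-segmented,
co-registered volumes; upstream preprocessing (brain extraction, tissue
segmentation, realignment, template warping, eddy/motion correction) is
deliberately out of scope.

## The MV-PVS detector

A voxel becomes a *candidate* when all three rules hold:

1. it lies inside the **eroded** white-matter mask;
2. its fractional deficit against the local neighborhood mean exceeds
   15%: $(\bar I_{N(v)} - I_v)/\bar I_{N(v)} > 0.15$ (strict);
3. its intensity ranks strictly below the 5th percentile of its
   neighbors.

Candidates are grouped under 26-connectivity (face, edge **and** corner
neighbors connect — "corner-to-corner" clustering), and clusters survive
only if their volume strictly exceeds 1 mm³.

Decisions behind the defaults:

* **Neighborhood**: a 5 mm spherical radius, excluding the center voxel.
  The neighborhood is computed over the full white-matter mask, while
  candidacy is restricted to the eroded mask; erosion (one pass of the
  6-connected structuring element) keeps boundary voxels — where partial
  voluming with gray matter and CSF mimics hypointensity — out of the
  candidate pool. The radius is a free parameter (`detection_params()`):
  large enough that a thin tubule cannot dominate its own reference
  statistics, small enough to remain local.
* **Deficit direction**: one-sided. PVS carry CSF and are dark on T1, so
  only hypointense deviations count; a `two_sided` flag restores the
  symmetric reading for sensitivity checks.
* **Percentile rank** is the fraction of neighbors *strictly below* the
  voxel's intensity, times 100. Ties do not count as below; on a constant
  plateau every voxel has rank 0, and rule (3) alone never fires because
  rule (2) cannot hold there.
* **Strictness**: both thresholds and the 1 mm³ bound are strict
  inequalities. At the 0.5 × 0.5 × 1.0 mm geometry a 4-voxel cluster
  (exactly 1.00 mm³) is removed and a 5-voxel cluster kept; at 0.94 mm
  isotropic a single voxel (0.83 mm³) is removed and a pair (1.66 mm³)
  kept.
* **Label order**: components are labeled by decreasing voxel count, ties
  broken by the smallest column-major linear index of a member. This
  makes label maps reproducible and lets the whole detector be compared
  voxel-for-voxel against a brute-force reference implementation, which
  the test suite does on seeded random volumes.

One behavior worth knowing: the percentile rule references each voxel
against *all* neighbors, including other dark voxels. When hypointense
structures are thick or dense enough to contribute a sizeable share of a
neighborhood (roughly more than ~10% of it), interior voxels start
ranking above the 5th percentile of their own kind and clusters thin or
fragment once noise breaks intensity ties. Real white-matter PVS are
sparse thin tubules, far below that regime; the synthetic phantoms used
for recovery testing are therefore noise-free, where exact intensity ties
give every tube voxel rank 0 and recovery is exact.

## Morphometry conventions

Cluster volume is voxel count × voxel volume. Length and width come from
a principal-component decomposition of the voxel-center world
coordinates: length is the projection extent onto the first principal
axis plus one voxel edge (the edge of the grid axis nearest that
principal axis), width the same for the second axis. The added edge
accounts for the half voxel of tissue on either side of the outermost
centers, and makes the convention collapse gracefully: a single voxel
reports its sorted edge lengths, a line of five 1-mm voxels reports
length 5 mm and width 1 mm. This is a deterministic, rotation-tolerant
*convention* — the quantity "width" is not uniquely defined for a digital
cluster, and alternative readings (mean cross-section, volume/length)
would differ; this is the main comparability caveat against any other
implementation. When the second principal axis is degenerate (collinear
clusters) the extent is zero and the convention returns the voxel edge
nearest whatever basis vector the eigendecomposition supplies; for near
axis-symmetric clusters the "nearest grid axis" choice can tie and is
then resolved arbitrarily but deterministically.

Per-subject summaries are the five burden metrics: cluster count and
total cluster volume per mm³ of segmented white matter, and the median
cluster volume, length and width (even counts average the middle two).
Subjects with zero clusters get zero densities and *missing* medians —
never zeros — so downstream models drop those records instead of biasing
toward small values.

## Tensor fit and the ALPS index

The DWI generator and the fitter share one model,
$S = S_0\,e^{-b\,\mathbf g^\top D\,\mathbf g}$. Fitting is ordinary least
squares on $\ln S$ with the 7-column design
$(1, -b g_x^2, -b g_y^2, -b g_z^2, -2bg_xg_y, -2bg_xg_z, -2bg_yg_z)$,
solved once for all voxels through a shared QR decomposition. Log-linear
OLS is exactly invertible on noise-free data (the round-trip error in the
tests is ~10⁻¹⁴) and adequate at the SNR of the simulated regime;
weighted or nonlinear variants would only matter near the noise floor.
Non-positive signals are clamped to a small floor before the log, with a
count reported. The default acquisition scheme is two b = 0 volumes plus
60 directions at b = 1000 s/mm²; since no gradient table is distributed
with the acquisition description, the directions are a deterministic
Fibonacci-hemisphere spread, which is approximately uniform and more than
sufficient for a single-tensor fit (any 3 × n unit-column matrix can be
supplied instead).

The ALPS index uses two 4-mm spherical ROIs placed at the
projection-fiber and association-fiber locations at the level of the
lateral ventricles — world coordinates (29, −4, 10) and (41, −4, 10) mm
in an MNI-like frame, interpreted through the image affine (template
registration is upstream of this package; synthetic volumes simply
declare an MNI-like affine). With x the left-right axis (the presumed
perivascular direction, perpendicular to the projection fibers running
along z and the association fibers along y):

$$\mathrm{ALPS} =
\frac{\mathrm{mean}(D_{xx}^{proj},\, D_{xx}^{assoc})}
     {\mathrm{mean}(D_{yy}^{proj},\, D_{zz}^{assoc})}$$

Diagonal tensor elements are averaged across each ROI *first*, then
combined — more robust to single-voxel outliers than averaging per-voxel
indices. The index is a pure ratio: isotropic tensors give exactly 1 and
uniform tensor scaling cancels. Because descriptions of the index
sometimes speak of the second and third *eigenvalues* rather than
frame-axis diffusivities, an eigenvalue-based variant is available
(`method = "eigen"`): per ROI it takes the eigenvalue of the ROI-mean
tensor whose eigenvector lies nearest the relevant axis. For axis-aligned
tensor fields the two conventions coincide; the diagonal form is the
default because it matches the index's original closed form.

## The synthetic cohort and the statistical models

`generate_cohort()` reproduces the two-campaign design: 8 HDBR subjects
imaged five times (days −13, −7, 29, 58, +10) and 11 HDBR+CO~2~ subjects
imaged six times (days −13, −7, 7, 29, +7, +13), sharing the BDC-7 and
HDT29 sessions; five HDBR+CO~2~ subjects are labeled SANS. Sex ratios
follow the study demographics (HDBR 2F:6M; HDBR+CO~2~ 5F:6M with SANS
3F:2M), ages are 34 ± 8 years truncated to [24, 55], and height/weight
are drawn from the campaign-level summary statistics — these fields exist
to exercise the covariate and demographics code, not to carry effects.
Each record is baseline + injected shift + subject intercept + residual;
variance components and injected shifts are expressed in units of the
metric's within-subject SD (by default 10% of its baseline mean), so "a
shift of 2" means two within-subject SDs for every metric. Baseline means
are order-of-magnitude values for healthy adult white matter (count
density 6 × 10⁻⁴ /mm³, volume fraction 2.5 × 10⁻³, median volume 5 mm³,
length 4 mm, width 1.2 mm, ALPS 1.5 — the neurotypical 1.4–1.6 range).

`fit_metric_model()` fits, per metric, the ordinary-least-squares model

```
value ~ timepoint * group + sex + age_centered
```

with timepoint categorical and releveled to the pre-bed-rest reference
(BDC-7), group either SANS status or campaign, α = 0.05 and **no**
multiplicity correction — the analysis is explicitly exploratory and all
individual p-values and 95% CIs are reported. Recovery timepoints (R+7,
R+13) are tested against the same reference only when a pre- to
in-bed-rest contrast was significant (a conditional gate, switchable via
`gate = FALSE`). SANS classification itself implements the either-eye,
any-sign rule with the strict 0.75 D hyperopic-shift threshold.
Demographic comparisons use equal-variance Student t-tests; per-metric
normality is summarised with Shapiro–Wilk statistics.

Two modeling notes:

* The data are repeated measures, but the default inference is plain OLS
  with model-based SEs, mirroring the stated analysis. A subject-level
  random intercept is available (`method = "lmer"`) for sensitivity
  checks. Because OLS assumes independent errors, the calibration
  simulations in the test suite generate cohorts with the
  between-subject component set to zero — they verify that the *test* is
  calibrated under its own assumptions. With a nonzero subject intercept
  the interaction tests become conservative (between-subject variance
  inflates the OLS SE while the paired structure removes it from the
  estimator), which is a property of the model/data mismatch, not of the
  implementation.
* With campaign grouping, only the shared BDC-7/HDT29 sessions identify
  both groups; callers subset to those timepoints (as the combined-cohort
  analysis script does).

## Problem sizes and verification

The test suite and the acceptance script exercise the chain at sizes
chosen to make every property measurable in seconds to a couple of
minutes on one CPU: detector-versus-brute-force equality on 10–20 seeded
random volumes of 12³–20³ voxels with a 2-mm neighborhood; tube recovery
on a 64³ phantom with ten axis-aligned tubes of radius 1–2 voxels at 30%
contrast (all ten recovered; width within one voxel edge of the tube
diameter, length within 1.5 edges of the axis length); tensor round
trips on random SPD tensors; the closed-form ALPS field (index 7/3, two
33-voxel ROIs); 1000 null replicates of the study-sized cohort for
type-I calibration; 150 replicates at 200 subjects per group for
interaction bias; and 25 replicates at 60 per group — where the
difference-in-differences power for a 2-SD shift exceeds 0.9 — for the
qualitative SANS pattern (No-SANS median MV-PVS volume dipping during
bed rest and partially rebounding in early recovery, SANS flat, equal at
baseline).

## What the phantoms do not emulate

The generators are deliberately minimal: tubes are finite cylinders
(membership by voxel center, no end caps, no partial voluming), white
matter is a uniform box, there is no cortical folding, no gray-matter
PVS, no bias field, and no scanner artifacts (Gibbs ringing, drift, eddy
currents) — the pipeline's preprocessing-free contract makes those
upstream concerns. Passing the recovery tests therefore shows the
*rules* are implemented exactly and that geometry is measured faithfully
under ideal contrast; it does not certify detection sensitivity on real
tissue, where contrast, texture and anatomy differ. Likewise the cohort
generator produces Gaussian variance components with known shifts — it
validates estimator calibration and power behavior, not the biological
effect sizes, and no size/count distribution of real PVS is claimed. The
original cohort's p-values are not reproducible from distributed data;
all statistical guarantees here are therefore property-based
(calibration, bias, qualitative-pattern recovery at simulation scale).
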