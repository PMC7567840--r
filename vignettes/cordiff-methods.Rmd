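---
title: "Models and methods behind cordiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cordiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordiff)
```

`cordiff` analyzes cervical spinal-cord diffusion MRI: it designs
multi-shell gradient schemes, fits single- and multi-compartment signal
models per voxel, condenses metric maps into per-subject ROI features,
and runs the group-difference / feature-selection / classification /
reproducibility cascade. This vignette explains the models, the
parameters that matter, the synthetic phantom that stands in for scanner
data, and the numerical and design choices made where more than one
reasonable option existed.

## Signal models

**Diffusion tensor.** Per voxel the log signal is linear in the six
tensor components and log S0. We first solve ordinary least squares,
then two weighted passes with weights equal to the squared predicted
signal — the standard correction for the log transform's
heteroscedasticity. Noiseless tensor data are therefore recovered
exactly (the suite checks agreement to 1e-6 with a closed-form
eigenvalue oracle, FA ≈ 0.8704 for eigenvalues (1.7, 0.2, 0.2)×10⁻³
mm²/s). Negative eigenvalues, which arise under noise, are clamped to
zero before FA and MD so FA stays in [0, 1]; MD is the mean of the
clamped eigenvalues. Signals are floored at 1e-6·S0 before the log.

**Ball-and-stick-and-stick.** The three-compartment model shares one
diffusivity `d` between an isotropic ball and two fully anisotropic
sticks. We estimate a per-voxel point fit rather than a posterior: the
analysis consumes only point maps (f1, f2, d), and a deterministic
optimizer keeps the pipeline reproducible and desk-scale. The
parameterization enforces every constraint by construction: `d = exp(p)`
(clamped to `exp(±20..10)` so line-search excursions cannot overflow),
fractions through a softmax over (ball, stick1, stick2) so f1, f2 ≥ 0
and f1 + f2 ≤ 1, sticks as spherical angles, and S0 profiled out in
closed form (it enters linearly). Each voxel starts from a
tensor-informed initialization (principal eigenvector, MD, FA) plus
seeded random restarts (default 5); the best residual wins, residual
ties break toward lower f2, and a restart that reaches a numerically
exact fit stops the search early. Two post-fit conventions: sticks are
sorted so f1 ≥ f2, and near-collinear sticks (|v1·v2| > 0.985) are
merged into one, because a single fiber population can be split across
both sticks at identical residual — an exact-fit degeneracy, not a
crossing. A voxel whose optimizer fails is flagged, never fatal.

**Crossing detection** is the literal rule f2 > 0.05 on the fitted
second stick, reported as a fraction of the mask.

## Gradient scheme design

Directions are placed by minimizing antipodal electrostatic energy: for
each pair, 1/‖xi−xj‖ + 1/‖xi+xj‖, summed within each shell plus a
0.5-weighted term over the union of all shells, so each shell and the
combined set are near-uniform. The two shells are optimized jointly;
samplers of this family do not standardize the coupling weight, and 0.5
balances per-shell against union uniformity. The optimizer is projected gradient descent on the
product of unit spheres: 2000 iterations cap, step halving on energy
increase, stop at relative energy change below 1e-10. At n ≤ 64 points
this is fast and, from a seeded random start, bit-reproducible. The
tests verify the optimized sets beat the best of large random ensembles
in energy and minimum folded angle.

## The phantom: what it emulates, what it does not

`simulate_cohort()` generates aligned, segmented C3–C6-like axial
volumes. Geometry is parametric — an elliptical cord with four GM horn
lobes and a commissural band — rather than atlas-based, so no external
template is needed while the crossing analysis still gets its
dorsal-horn/commissure topology. The grid default is 48×48×12 voxels at
0.65×0.65×3 mm, which keeps a 60-record cohort simulation in the
seconds range; smaller grids are used in some tests purely as a
resolution choice and are stated where used.

Baselines were chosen once as order-of-magnitude values anchored to the
ranges the analysis targets (no quantitative ground truth exists for
them): WM d = 1.5, GM d = 1.0 (10⁻³ mm²/s), WM f1 = 0.65, GM f1 = 0.35,
S0 = 100. The channel noise sigma = 12 puts the b = 550 shell SNR near
5.5 and the b = 1000 shell near 4, matching the low-SNR regime of cord
dMRI. Patient groups modify the field only through multipliers: the
WM–GM diffusivity gap shrinks to 0.75 (mild) and 0.55 (severe) of the
control gap with GM held fixed, WM f1 scales by 0.95/0.90, WM voxel
dispersion inflates by 1.2/1.4. With all multipliers at 1 a patient
field is bit-identical to a control field under the same seed, which the
tests exploit.

Between-subject variation has a deliberate structure: a shared
cord-level diffusivity scale (SD 5%) plus small independent WM/GM
tissue scales (SD 2%) plus an f1 scale (SD 5%). The shared component
cancels in the WM−GM difference markers — precisely the property that
makes the diffusivity gradient a robust subject-level marker — while
the tissue-specific part survives as honest between-subject noise in
those markers.

Crossing fibers are placed in WM voxels adjacent to dorsal-horn or
commissure GM, up to the configured prevalence (10% of cord voxels by
default), with transverse in-plane secondary sticks and f2 drawn in
0.12–0.28; the primary stick is superior–inferior everywhere. Test–retest
sessions share ground truth and differ only in the noise stream, so
session differences are pure measurement noise. Air outside the cord is
signal-free, giving the SNR estimator a genuine Rayleigh background.

What the phantom does **not** model: susceptibility or motion artifacts,
ghosting, fat-suppression failure, partial-volume boundaries,
vertebral-level trends along the cord, or realistic spatial noise
correlation. Passing the suite therefore demonstrates correctness of the
estimators and cascade under the stated noise model, not robustness to
scanner artifacts.

Two map routes feed the feature stage. `map_source = "fit"` regenerates
each subject's DWI and fits both models voxel-wise — the full route.
`map_source = "truth"` (default) uses the ground-truth maps (FA and MD
from the equivalent tensor d[(1−f)I + f1 v1v1' + f2 v2v2'], computed in
closed form from tensor invariants) plus seeded per-voxel Gaussian
estimation noise (FA/f1 0.05, MD 0.08, d 0.10×10⁻³). The decoupling is a
design choice: fit accuracy is validated on its own (noiseless recovery,
SNR-20 Monte Carlo), and the statistical cascade is validated on
hundreds of cohorts, which would be intractable if every cohort demanded
~10⁵ nonlinear refits. One consequence to keep in mind: iid map noise
averages away in ROI means, so the phantom's test–retest CVs are
optimistic relative to real repeat scans.

## ROI features

Descriptive statistics use divide-by-n (population) moments and
non-excess kurtosis (Gaussian → 3); a zero-variance ROI reports
skewness/kurtosis as missing rather than NaN. The heuristic parameters
integrate a Gaussian-kernel density with the normal-reference
(Silverman, `bw.nrd0`) bandwidth over fixed intervals; the interval mass
is evaluated exactly through the normal CDF of each kernel, so H ∈ [0,1]
and is monotone in the interval by construction. The 54-column feature
vector is 40 descriptive + 8 WM−GM differences + 6 heuristics — 54
parameters; a count of 56 is sometimes quoted for feature sets of this
family, but no further parameters are identifiable from the enumerable
construction, so 54 is what the table exposes.

**SNR.** Per shell: mean DWI intensity inside the cord, excluding the
first and last four slices, divided by √(2/(4−π))·σ_air. Two choices
the estimator definition leaves open: σ_air is the pooled SD of air-voxel magnitudes
over the shell's own volumes (keeping the estimate per-shell and
consistent with the Rayleigh identity SD = σ·√((4−π)/2)), and the "air
half" of the field of view is the high-index half of in-plane axis 2,
with the phantom cord placed in the other half.

**Mutual information** uses q = 64 equal-width bins over the region's
range (a bias/variance compromise at cord-ROI sizes; configurable),
natural logs, and 0·log 0 = 0. The label coding includes background = 0,
so the default region is the cord's bounding box dilated by 2 voxels,
ensuring all three labels occur; cord-only evaluation is available via
`region = "cord"` for the stricter reading.

## Statistical cascade

Rank-sum tests are two-sided, exact by enumeration when both groups have
at most 10 subjects and no ties, normal approximation with tie and
continuity correction otherwise; the family-wise threshold is 0.05/6 for
the six pairwise comparisons of four groups. Percent differences are
100·(patient/control − 1), rounded to two decimals, reported in the
patient-vs-control direction only (the operation is not antisymmetric).
ANCOVA compares controls against pooled patients with age as covariate;
the group term's partial F is computed explicitly from the two fits'
residual sums of squares so that a zero increment cleanly yields F = 0,
p = 1. The radiculopathy screen is per-parameter rank-sum at
uncorrected 0.05.

Stepwise regression on the ±0.5 class signal enters candidates at
coefficient p < 0.05 and removes at p > 0.10, the common
forward-with-removal pairing.
Selection is deterministic given column order (ties by smaller entry p,
then earlier column). K-means uses z-scored features (scale-dominated
clusters would otherwise defeat the point of selection), seeded
k-means++ initialization and 100 restarts; both are exposed as configuration. The two
clusters map to distinct classes — of the two possible assignments, the
one agreeing better with the expert labels, which equals per-cluster
majority except in the degenerate case where both clusters lean toward
the majority class. Sensitivity and specificity take patients as
positive.

Reproducibility: the pair CV is sample SD over mean (√2·|Δ|/(2·mean));
CVs are computed for the mean/median WM/GM parameters only, because
shape statistics have near-zero means that make CV meaningless. Min–max
normalization of session differences pools across protocols per
variable; a degenerate pooled range (min = max) maps to 0 by convention.
Signed-rank protocol comparisons drop zero differences before ranking
and Bonferroni-multiply by the number of protocol pairs, capped at 1.

## Degenerate inputs and tie-breaks, collected

* b0 directions are stored as zero vectors; weighted directions are
  renormalized on read and must be unit to 1e-6 on construction.
* Tensor fits require ≥ 7 volumes including a b0 and at least one
  weighted volume; anything less is an error, not a silent NA.
* An all-identical feature matrix is a degenerate clustering error; a
  two-subject clustering assigns each subject its own cluster.
* A zero control median makes the percent difference undefined (error).
* A constant metric map has zero entropy and zero mutual information.
* An empty radiculopathy subgroup skips the screen with a warning.

## Problem sizes used by the validation suite

The suite fits 10³ noiseless tensor voxels and 10³ Rician-noise
Monte-Carlo ball-stick voxels, simulates 500 null feature cohorts for
the family-wise calibration band, and runs the end-to-end cascade over
20 seeded cohorts at the default group sizes (60 records each),
checking the median sensitivity and specificity. These sizes were chosen
to give stable Monte-Carlo estimates at interactive runtimes.

## Known limitations

* The ball-stick fit is a point estimate; no posterior uncertainty, and
  equivalence with sampling-based reference fits is not claimed — only
  recovery of simulated ground truth.
* The phantom's artifact-free geometry means registration, segmentation
  and distortion correction are entirely out of scope; inputs are
  assumed aligned and labelled.
* Tract-specific and vertebral-level-resolved features are not
  implemented; features pool one C3–C6-like ROI per tissue.
* Multi-class severity classification (mild vs severe) is out of scope;
  the classifier separates controls from pooled patients.
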