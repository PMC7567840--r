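# cordiff

Quantitative microstructural analysis of cervical spinal cord diffusion
MRI (dMRI), from acquisition-scheme design to patient-control
classification.

Degenerative cervical cord compression is often present long before any
clinical sign of myelopathy. Diffusion MRI can expose the underlying
microstructural injury at that presymptomatic stage, but doing so reliably
needs a carefully designed multi-shell acquisition, a crossing-fiber
signal model, and region-of-interest (ROI) statistics that are robust at
the low SNR of spinal-cord imaging. `cordiff` implements that full
analysis chain for researchers working on quantitative cord imaging, and
ships a parametric spinal-cord phantom so every stage can be exercised and
validated without any scanner data.

## What the package computes

**Signal models.** Per voxel, the diffusion tensor (DTI, 7 parameters,
log-linear weighted least squares) giving fractional anisotropy FA and
mean diffusivity MD; and the three-compartment ball-and-stick-and-stick
model (8 parameters),

    S_k = S0 [ (1 - f1 - f2) e^(-b_k d)
             + f1 e^(-b_k d (g_k . v1)^2)
             + f2 e^(-b_k d (g_k . v2)^2) ],

with shared diffusivity `d`, stick orientations `v1`, `v2` and partial
volumes `f1 >= f2`. Voxels with a significant second stick (`f2 > 0.05`)
are counted as crossing fibers, expected near the dorsal horns and the
anterior white commissure.

**Scheme design.** Antipodal electrostatic-repulsion optimization of
multi-shell gradient direction sets (e.g. the two-shell 21 + 42 direction
scheme at b = 550/1000 s/mm^2 with 7 b0 volumes), with FSL-style
bval/bvec readers and writers.

**ROI features.** Per subject and metric map (FA, f1, MD, d) over the WM
and GM of a C3-C6-like slab: mean, median, SD, skewness, kurtosis; the
WM-GM differences of means and medians (the diffusivity *gradient*, the
headline separating marker); and six heuristic parameters

    H = integral over [x1, x2] of g(x) dx,

the mass of a Gaussian-kernel density fit `g` inside fixed metric
intervals (FA: 0.47-0.67; f1: 0.30-0.55; MD: 0.84-1.26; d in WM:
1.70-2.20; d in GM: 1.00-1.48; diffusivities in 1e-3 mm^2/s). That is 54
named parameters per subject-session, following the `metric | w/g/wg |
M/m/S/SK/K/H` shortcut convention (e.g. `MDwgm`, `f1wSK`).

**Protocol quality.** Shell-wise SNR from raw volumes,
`SNR = I_SC / (sqrt(2/(4-pi)) * sigma_air)`, with the Rayleigh background
correction for magnitude noise; and the mutual information
`I = E_a + E_b - E_ab` (nats) between each metric map and the 3-level
tissue labels.

**Statistical cascade.** Wilcoxon rank-sum tests over all six pairwise
group comparisons at the family-wise threshold 0.05/6; percent
differences of group medians; age-adjusted ANCOVA; radiculopathy
post-hoc screens; forward stepwise regression on the +-0.5 class signal;
seeded k-means++ classification scored as sensitivity/specificity against
expert labels; and test-retest coefficients of variation with min-max
normalized session differences and signed-rank protocol comparisons.

**Phantom.** `simulate_cohort()` generates the full synthetic study: 7
young controls scanned twice, 13 age-comparable controls, 18 mild and 15
severe compression patients (13 of 33 patients with radiculopathy), each
with segmented butterfly-GM cord masks, ground-truth microstructure with
group effects (reduced WM-GM diffusivity gradient in patients), two-shell
DWI via the forward model, and Rician noise at cord-realistic SNR.

## Worked example

```r
library(cordiff)

generate_multishell_scheme(c(21, 42), c(550, 1000), n_b0 = 7, seed = 1)
#> <gradient_scheme> 70 volumes: 7 b0 + 63 weighted
#>   shell 1: 21 directions at b = 550 s/mm^2
#>   shell 2: 42 directions at b = 1000 s/mm^2

result <- run_pipeline(pipeline_config(seed = 1))
result
#> <pipeline_result>
#>   60 records, 26 significant parameter(s)
#>   selected: FAwS, FAwSK, dwH
#>   SE = 100.00%, SP = 92.31%

glance(result$model)
#> # A tibble: 1 × 7
#>       r  rmse statistic  p.value r.squared     n n.selected
#>   <dbl> <dbl>     <dbl>    <dbl>     <dbl> <int>      <int>
#> 1 0.888 0.217      52.3 3.08e-14     0.789    46          3
```

Reading the output: 26 of the 54 ROI parameters separate the
age-comparable controls from a patient group at the 0.05/6 family-wise
threshold on this synthetic cohort; stepwise regression keeps three
non-redundant ones; k-means on those three recovers the expert
control/patient split with 100% sensitivity and 92.31% specificity
(one control clustered with the patients). The model block is the
stepwise fit of the +-0.5 class signal: correlation r = 0.888 between
class and fitted signal, RMSE 0.217, F = 52.3, and 78.9% explained
variance over the 46 classified subjects.

Results are tibbles throughout, so the usual verbs apply —
`result$tests |> dplyr::filter(significant)`, `tidy(result$model)`,
`autoplot(maps$FA)`, `plot_group_features(result$features, c("dwgm",
"MDwgm"))`.

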