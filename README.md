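# longmdt

Longitudinal structural MRI morphometry with subject-specific non-linear
templates and spatio-temporal regularization of the deformation trajectory —
plus the ground-truth 4D phantom machinery needed to validate every stage
without external data.

## What it is for

Measuring how brain structures change across repeated MRI visits (whole-brain
atrophy, ventricular enlargement, hippocampal loss) is noisy when every visit
is processed independently: each time-point carries its own registration
noise, and per-subject trajectories become erratic even though the anatomy
changes slowly and smoothly. `longmdt` implements the longitudinal
alternative:

1. **Cross-sectional preprocessing** — patch-based (non-local-means)
   denoising, intensity non-uniformity correction, percentile-anchored
   intensity normalization, hierarchical linear registration into a common
   stereotaxic space.
2. **Subject-specific templates** — an iterative linear template, then a
   non-linear *minimum deformation template*: every visit is registered to
   the evolving template with a hierarchical node-grid matcher (local
   cross-correlation, coarse-to-fine, elastic-style smoothing), the mean
   deformation is removed each iteration (`phi_t = psi_t ∘ inv(mean psi)`) so
   the template favors no visit, and visit-specific intensity non-uniformity
   is corrected against the template.
3. **Spatio-temporal (4D) regularization** — the package's core: per-visit
   deformations are treated as a trajectory `T(v, t)`, reconstructed
   spatially through a first-order Taylor model with neighborhood-averaged
   Jacobians, and regressed linearly against the visit times per voxel:
   `T*(v,t) = T0(v) + T1(v)·t`. Spatially incoherent, temporally inconsistent
   registration noise is suppressed; spatially affine, temporally linear
   change passes through exactly.
4. **Jacobian volumetry and power analysis** — structure volumes by
   integrating `det(I + ∇φ_t)` over structure masks; scan-rescan variability
   metrics (`VC`, `aVC`); longitudinal change (`longVC`); the random-slope
   mixed model `longVC_it = (β1 + β2·Group + b_i)·t + ε`; sample-size-per-arm
   estimates from the closed-form rate-of-change formula
   `n = 2(z_{1−α/2}+z_{power})² σ² (1−ρ) / (m s_x² d²)` with parametric
   bootstrap confidence intervals.

Three measurement modes reproduce the classic comparison: **CS**
(cross-sectional, every visit independently registered to a common
reference), **IT** (subject template without the 4D constraint), **LIT**
(the full longitudinal mode).

## A worked example

```r
library(longmdt)

# A scan-rescan study: 4 subjects scanned 4 times in one week, no true change
spec <- phantom_spec(seed = 1)
ds   <- simulate_scan_rescan(spec, n_subjects = 4)
res  <- run_pipeline(ds, pipeline_config(), modes = c("CS", "LIT"))
print(res)
#> <pipeline_result> mode LIT: 4 subjects, 4 structures
#>   median aVC CS   brain          0.103 %
#>   median aVC CS   hippocampus_l  1.119 %
#>   median aVC CS   hippocampus_r  1.053 %
#>   median aVC CS   ventricles     0.485 %
#>   median aVC LIT  brain          0.099 %
#>   median aVC LIT  hippocampus_l  0.533 %
#>   median aVC LIT  hippocampus_r  0.395 %
#>   median aVC LIT  ventricles     0.509 %
```

The absolute percent volume change (`aVC`) of a structure across same-week
rescans measures pure measurement variability — there is nothing real to
detect. The longitudinal mode (LIT) cuts the hippocampal variability
roughly in half relative to independent per-visit processing (CS); for
large high-contrast structures (whole brain, ventricles) both modes sit
near the same discretization floor at this phantom scale, so their medians
can tie.

On a two-group cohort (visits at 0/6/12/24 months, AD-like vs control
atrophy rates), `power_report()` produces the sample-size table: annual
rates per group from the mixed model, the detectable effect (25% of the AD
rate by default), and subjects per arm at 80% power:

```r
co  <- simulate_cohort(phantom_spec(seed = 2), n_nc = 6, n_ad = 6)
out <- run_pipeline(co, pipeline_config())
power_report(out$change_table)
#>       structure rate_nc rate_ad beta2 se_beta2 effect n_per_arm ...
#>           brain   0.419    1.98  1.56    0.214  0.494         4
#>   hippocampus_l   1.685    3.93  2.25    0.781  0.983        10
#>   hippocampus_r   0.325    3.63  3.30    1.002  0.907        18
#>      ventricles  -4.699   -9.09 -4.39    1.345  2.272         6
```

(Desk-scale phantom runs; exact values vary with the seed. The generator's
true NC/AD rates are 0.66/1.84 %/yr of volume loss for the brain,
3.86/9.04 %/yr of growth for the ventricles — growth appears as negative
longVC — and roughly 0.9/3.4 %/yr of loss for the hippocampi.)

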