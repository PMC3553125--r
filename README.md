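# daysgained

Patient-specific **untreated virtual controls** (UVC) and the **Days
Gained** treatment-response metric for glioblastoma, from routine MRI
segmentations.

Glioblastomas vary enormously in how fast they grow, so comparing a
post-treatment scan with a pre-treatment scan conflates therapy effect with
intrinsic kinetics. This package instead calibrates a growth model to each
patient, simulates how *that* tumour would have grown untreated inside the
patient's own brain geometry, and scores the therapy by how many days of
imageable growth it bought. It is intended for computational-oncology
researchers working with co-registered T1Gd/T2 tumour masks, and for method
development on fully synthetic ground-truth patients.

## The model in brief

Normalised tumour cell density `c` follows the proliferation-invasion
(Fisher-KPP) equation

    dc/dt = div(D grad c) + rho c (1 - c)

inside the brain mask (zero flux at its boundary), with patient-specific net
diffusivity `D` (mm²/day) and proliferation rate `rho` (1/day). Density at
or above 80% of the tissue carrying capacity (10⁸ cells/cm³) is visible on
T1Gd MRI; 16% on T2. From two pre-treatment scans:

* the T1Gd spherically-equivalent (SE) radius secant gives the front
  velocity `v = 2 sqrt(D rho)`;
* the T2−T1Gd SE-radius margin gives the infiltration length
  `l = sqrt(D/rho)` via the travelling-front contour separation
  (`front_margin_constant()` ≈ 6.106 for the 0.80/0.16 thresholds).

The simulation starts from the second pre-treatment scan, eroded by 20% of
its SE radius and ramped with Gaussian shoulders, regrows it to the observed
size, and continues to the post-treatment day. The **Days Gained score** is
`t_post − t*`, where `t*` is the time at which the simulated T1Gd SE-radius
curve matches the observed post-treatment radius (chord extrapolation when
the observation falls outside the curve; negative scores mean the tumour
outgrew its own virtual control). A constrained Kaplan-Meier scan
(`threshold_scan()`) then finds the score cutpoint that best separates
survival outcomes, requiring at least 20% of the cohort on each side.

## Worked example

Everything below is synthetic — the generator plants a known 60-day therapy
effect and the pipeline recovers it:

```r
library(daysgained)

dom <- make_brain_domain()            # 64^3 spherical brain, 1 mm voxels
vp  <- make_virtual_patient(response_days = 60, domain = dom, seed = 1)
score <- score_observations(vp$pre1, vp$pre2, vp$post$t1gd_mask,
                            vp$post$day, dom)
score
#> <days_gained_score> 57.2 days (matched t = 92.8, r_post = 13.06 mm, interpolated_on_curve)
tidy(attr(score, "params"))
#> # A tibble: 4 × 3
#>   term                estimate unit
#>   <chr>                  <dbl> <chr>
#> 1 D                     0.0465 mm^2/day
#> 2 rho                   0.0180 1/day
#> 3 velocity              0.0580 mm/day
#> 4 infiltration_length   1.61   mm
```

The planted 60-day response is recovered as 57.2 days; the estimated
kinetics sit within ~10% of the generator's true `D = 0.05`, `rho = 0.02`
(the residual bias is the finite-radius curvature correction discussed in
the methods vignette). At cohort level:

```r
co   <- make_survival_cohort(200, threshold = 100, hazard_ratio = 3, seed = 7)
scan <- threshold_scan(co)
glance(scan)
#> # A tibble: 1 × 6
#>   optimal_threshold     optimal_p     n min_fraction n_admissible endpoint
#>               <dbl>         <dbl> <int>        <dbl>        <int> <chr>
#> 1                99 0.00000000306   200          0.2          188 PFS
autoplot(scan)   # log-rank p across all candidate thresholds
```

A 3-fold hazard reduction planted at score 100 is located at threshold 99.
For file-based use, `run_patient("patient.yaml")` executes the whole chain
(volumes in NIfTI, report as JSON) and `run_cohort("cohort.csv")` scans a
delimited cohort table; `inst/cli/daysgained.R` exposes both as shell
subcommands together with `make-fixtures` and `simulate`.

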