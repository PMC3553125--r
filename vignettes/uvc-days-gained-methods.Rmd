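---
title: "Untreated virtual controls and the Days Gained response metric: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untreated virtual controls and the Days Gained response metric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(daysgained)
```

## The problem

Response assessment in glioblastoma is confounded by patient-to-patient
variability in growth kinetics: a fast-growing tumour that responds strongly
to therapy can still be larger at follow-up than a slow-growing tumour that
barely responded. `daysgained` implements a model-based alternative: from two
pre-treatment MRI segmentations it calibrates a patient-specific
reaction-diffusion growth model, simulates how the tumour *would* have grown
untreated inside that patient's brain (the *untreated virtual control*, UVC),
and expresses the observed post-treatment tumour size as the number of days
of imageable growth the therapy bought — the *Days Gained* score. At the
cohort level, a constrained Kaplan-Meier threshold scan relates scores to
progression-free and overall survival.

## The growth model

Tumour cell density $c(\mathbf{x},t)$, normalised to the tissue carrying
capacity $K = 10^8$ cells/cm$^3$, evolves by the proliferation-invasion
(Fisher-KPP) equation

$$\frac{\partial c}{\partial t} = \nabla\cdot(D\,\nabla c) + \rho\, c\,(1-c),$$

with net diffusivity $D$ (mm$^2$/day) uniform inside the brain mask, net
proliferation rate $\rho$ (1/day), and zero-flux conditions on the brain-mask
boundary, so tumour cells do not cross the skull or ventricles and total cell
number is exactly conserved when $\rho = 0$. Two derived scales matter
throughout:

* the asymptotic radial front velocity $v = 2\sqrt{D\rho}$;
* the infiltration length $\ell = \sqrt{D/\rho}$, the width scale of the
  invisible tumour gradient beyond the imaging threshold.

Imaging enters through detection thresholds: voxels with $c \ge 0.80$ are
taken to be visible on gadolinium-enhanced T1 MRI, and voxels with
$c \ge 0.16$ on T2/FLAIR. Both fractions are configurable
(`detection_thresholds()`). A segmented volume $V$ is reduced to its
spherically-equivalent (SE) radius $(3V/4\pi)^{1/3}$.

## Estimating patient kinetics

`estimate_parameters()` inverts two travelling-wave relations:

1. **Velocity.** The T1Gd SE radius secant between the two pre-treatment
   scans gives $v$; at least five days must separate the scans for the
   change to be measurable.
2. **Margin.** The T2-minus-T1Gd SE-radius margin $\Delta r$ at the second
   scan measures the infiltration gradient: $\ell = \Delta r / \kappa$, with
   $\kappa$ the dimensionless separation of the 0.80 and 0.16 contours of
   the travelling front.

Then $D = (v/2)\,\ell$ and $\rho = (v/2)/\ell$.

The choice of $\kappa$ deserves care. The classical linearisation treats the
front's leading edge as a pure exponential $e^{-x/\ell}$, giving
$\kappa = \ln(0.80/0.16) = \ln 5 \approx 1.609$. But the 0.80 contour lies in
the saturated region of the front, not in its tail, and the critical-speed
front decays like $z\,e^{-z}$ rather than a plain exponential. Solving the
front equation $u'' + 2u' + u(1-u) = 0$ (by shooting forward along the
unstable manifold of the $u=1$ saddle; `front_profile()`) gives the actual
contour separation $\kappa = 6.106$ — almost four times the tail estimate.
Using the full-front $\kappa$ (`margin_rule = "front_profile"`, the default)
makes the estimator consistent with the model's own simulated profiles, which
is what a round-trip of simulation and estimation must satisfy; the
tail rule is kept as `margin_rule = "exponential_tail"` for comparison with
the older convention. The margin is read from the second (later) scan by
default because that scan also seeds the simulation; `margin_source = "mean"`
averages both.

## Building the initial condition

Simulations start from the second pre-treatment scan, not from a point
source. The construction (`build_initial_condition()`):

1. erode the T1Gd mask perimeter-by-perimeter (6-connected, so one pass
   strips a one-voxel layer) until its SE radius has dropped by 20%
   (`erosion_fraction`, configurable), recording the millimetres removed;
2. erode the T2 mask by the same number of millimetres;
3. set density 0.80 inside the eroded T1Gd region;
4. between the eroded T1Gd and T2 surfaces, let $d_1, d_2$ be the Euclidean
   distances (mm) to the two surfaces and $u = d_1/(d_1+d_2)$; density
   follows the Gaussian ramp $0.80\,e^{-(au)^2/2}$ with
   $a = \sqrt{2\ln(0.80/0.16)}$, so it reaches exactly 0.16 at the T2
   surface;
5. beyond the eroded T2 surface, density continues as
   $0.16\,e^{-d_2^2/(2\sigma^2)}$ with $\sigma = \Delta r_{SE}/a$ tied to the
   eroded SE-radius margin only — by construction independent of the
   distance to the T1Gd perimeter;
6. clip to $[0,1]$, zero outside the brain, floor values below $10^{-6}$.

The ramp parameterisation is this package's concrete choice; it is pinned
down by the property the construction must serve: thresholding the initial
field at 0.80/0.16 returns exactly the eroded masks (asserted in the test
suite). The erosion exists so the simulated tumour *regrows into* the
observed geometry rather than starting at the observed boundary; tumours so
small that erosion would consume them fall back to the last non-empty mask
with a warning rather than failing the pipeline.

## The solver

Explicit forward Euler with a 7-point Laplacian in flux form: a face whose
neighbour is outside the brain mask carries no flux. The time step obeys
$\Delta t \le 1/(2D\sum_i h_i^{-2})$ (equal to $h^2/6D$ on an isotropic
grid); the automatic choice takes 90% of that bound, additionally capped at
$0.2/\rho$ and at the sampling interval. Values are clipped to $[0,1]$ only
to absorb round-off, and the clipped magnitude is accumulated and reported
(`clip_total`) so numerical health is visible. Oversized user-supplied steps
are rejected before stepping, not after a NaN. The solver is fully
deterministic.

`simulate_uvc()` records the growth curve — T1Gd and T2 SE radii of the
thresholded density plus total cell count — at a configurable sampling
interval (default 1 day), always including both endpoints.

### Clock alignment

Because the initial condition is eroded, the simulation needs
$\approx \mathrm{mm\ removed}/v$ days of regrowth before it matches the scan
it came from. `uvc_growth_curve()` therefore shifts the simulation clock so
that the moment the simulated T1Gd SE radius reaches the *observed*
(uneroded) radius is labelled as the second pre-treatment day, extending the
run as needed to cover the post-treatment day. Without this alignment every
Days Gained score would be offset by the regrowth time (tens of days at
typical kinetics).

## Days Gained

`days_gained()` finds where the piecewise-linear UVC curve of T1Gd SE radius
crosses the observed post-treatment radius and reports
$\mathrm{score} = t_\mathrm{post} - t^*$. Non-monotone curves use the
earliest crossing (the conservative choice — it yields the smaller score).
If the observed radius lies below the curve's first sample or above its last,
$t^*$ is extrapolated along the chord through the curve's endpoints,
consistent with the near-linear radial expansion the model predicts: a
tumour smaller than the simulation's start scores more than the elapsed
time, and a tumour larger than the untreated prediction scores negative. A
flat chord with an out-of-range radius has no defined score and errors. Only
the T1Gd radius drives the score (it is the modality that discriminates
survival best); the score object carries a modality tag so T2 or total-cell
variants remain possible.

## Survival analysis

Kaplan-Meier curves and the two-group log-rank test go through the standard
`survival` package (`survfit`/`survdiff`); the test suite checks them
against hand-computed product-limit values and an independently implemented
brute-force risk-set oracle. The contribution here is the constrained scan
(`threshold_scan()`): every candidate threshold (by default each integer day
across the observed score range) splits the cohort into *below* versus
*at-or-above*; a split is admissible only if both groups hold at least 20%
of the cohort (`min_fraction`); the optimum is the admissible threshold with
the smallest log-rank p, ties going to the smallest threshold. No
multiple-testing correction is applied — the scan's purpose is cutpoint
*selection*, and the full p-map is returned (and plotted by `autoplot()`) so
the selection landscape is visible. PFS is clocked from the start of
cytotoxic therapy and OS from diagnosis; records carry an endpoint tag and
supplying times on the right clock is the caller's contract.

## Synthetic patients and cohorts

Nothing in the pipeline can be validated on public data (patient MRIs are
not deposited), so `make_virtual_patient()` builds ground-truth tumours with
known kinetics: a spherical (or ellipsoidal, or constricted two-lobe) brain
mask, a simulation seeded with the established travelling-front profile, and
observations fabricated by thresholding the simulated density at the scan
days. Therapy response is planted by *time-shifting*: the post-treatment
observation shows the ground-truth tumour as it was `response_days` earlier,
which makes the expected Days Gained score equal to `response_days` exactly
— no other construction guarantees the metric's target value.

Two generator choices matter:

* **Mature-front seeding.** Pulled (Fisher-KPP) fronts approach their
  asymptotic speed and width only like $1/t$ — the Bramson logarithmic
  delay. Seeded from a Gaussian blob, the simulated margin and velocity are
  still tens of percent from their asymptotes after 600 days, which no
  64 mm domain can accommodate. A glioblastoma at presentation has grown
  for years, so seeding with the established front profile is the realistic
  emulation *and* puts the virtual tumour in the wave regime the estimator
  assumes from day one.
* **Reference conditions.** Defaults are $D = 0.05$ mm$^2$/day,
  $\rho = 0.02$/day (velocity $\approx 23$ mm/year, infiltration length
  1.6 mm — median glioblastoma kinetics), a 64$^3$ voxel spherical brain at
  1 mm spacing, a seed T1Gd radius of 8 mm, and scans at days 40, 70 and
  150. These were chosen so the full T2 abnormality — which extends
  $6.1\,\ell \approx 10$ mm beyond the T1Gd front — stays clear of the
  domain wall for the whole simulated course.

`make_survival_cohort()` draws Days Gained scores from a clipped normal
(mean 134, sd 111, range $-77$ to $512$ — the reported spread of real
cohorts) and exponential event times whose hazard drops by a chosen ratio at
and above a planted threshold, with independent exponential censoring.

What the generator does *not* emulate: MRI intensities and segmentation
ambiguity (only masks and density fields are produced; optional boundary
"jiggle" noise is a crude stand-in), anisotropic or multifocal growth,
gray/white-matter diffusivity contrast, oedema dynamics, and
pseudo-progression. Passing tests therefore demonstrate internal consistency
of the method under its own model, not clinical accuracy.

## Numerical choices and validation results

The test suite and `scripts/acceptance.R` recompute, from scratch:

* **Front speed** — on a homogeneous 64$^3$ grid at $D = 0.1$,
  $\rho = 0.025$, the late-window slope of the T1Gd SE radius is within 10%
  of $2\sqrt{D\rho} = 0.1$ mm/day; the residual deficit is the curvature
  drag $2D/r$ of a spherical front.
* **Logistic limit** — with $D = 0$ the solver matches the logistic closed
  form to $10^{-3}$ at $\Delta t = 0.1$ day.
* **Conservation** — with $\rho = 0$ total cells are conserved to relative
  $10^{-8}$ in a constricted two-lobe mask.
* **Parameter recovery** — estimating from two synthetic observations of a
  known-$(D,\rho)$ tumour recovers both within 15% (measured: $D$ about 7%
  low, $\rho$ about 10% low at the reference conditions; the residual bias
  is the finite-radius curvature correction that the planar front relations
  ignore).
* **Planted Days Gained** — responses of 0/30/60/120 days are recovered
  within $\pm 7$ days end to end. The residual few-day bias is understood:
  the secant velocity slightly underestimates the instantaneous speed, and
  the UVC re-applies curvature drag the secant already contains.
* **Survival** — a cohort of 200 with hazard ratio 3 planted at score 100
  yields an optimum within $\pm 15$ days of 100; under the null the
  log-rank p at the planted split is uniform across 1000 seeds
  (Kolmogorov-Smirnov sanity check), while scan *optima* are small-biased by
  selection, as expected, yet not uniformly extreme.
* **Erosion contract** — on rasterised balls the 20% erosion stops at the
  first iteration at or below target, within one layer's reduction.

Problem sizes throughout (64$^3$ voxels, 80–150 simulated days, cohorts of
60–200, 1000-seed null calibrations) are the package's reference validation
conditions; each acceptance run completes in well under a minute of compute
per item on a single core.

## Degenerate inputs and tie-breaks

* Empty masks, non-nested T1Gd/T2 pairs, and tumour voxels outside the brain
  are validation errors or repaired with explicit warnings (union / clip).
* Erosion that would consume the tumour errors by default; the pipeline
  requests the fall-back (last non-empty mask, warning).
* Equal pre-treatment radii (zero velocity) and non-positive T2 margins are
  estimation errors — the model cannot be calibrated from them.
* Multiple curve crossings take the earliest; ties in the threshold scan
  take the smallest threshold; `which.min` semantics make both
  deterministic.
* All-censored cohorts produce a valid flat Kaplan-Meier curve plus a flag.

## Known limitations

* $D$ is uniform inside the brain mask; gray/white differential migration is
  out of scope by design (a config hook records the decision).
* The UVC is untreated by definition; therapy terms are not modelled.
* The planar-front inversion underestimates $D$ by order $\ell/r$ for small
  tumours; users with very small lesions should expect biased kinetics.
* Highly anisotropic tumours lose lobes under SE-radius erosion — the
  spherically-equivalent reduction deliberately minimises anisotropy
  effects, but spatially localised response measures are out of reach.
* Registration and segmentation are preconditions, not features: all masks
  must share one voxel grid.
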