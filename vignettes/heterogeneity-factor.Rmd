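---
title: "The heterogeneity factor and its prognostic evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The heterogeneity factor and its prognostic evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfpet)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, and the choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The measurement model

All image quantities live on a 3D grid of standardized uptake values
(SUV, dimensionless) with physical voxel spacing. The classical
parameters are computed per lesion within a containment mask (the
volume of interest a physician would draw):

* `SUVmax` is the maximum SUV in the mask.
* The **MTV isocontour threshold** is the mean SUV of a
  mediastinal-style background reference region plus two standard
  deviations. We use the *sample* SD (n−1) by default — the convention
  of the surrounding biostatistics software — with the population SD
  available; at the region sizes involved (hundreds of voxels) the two
  differ negligibly.
* **MTV** is the volume (cm³ = mm³/1000) of mask voxels with
  SUV ≥ threshold. The comparison is inclusive: ties at the threshold
  belong to the lesion. No connected-component filtering is applied
  inside the mask — the mask is the containment contract.
* **SUVmean** is the mean over the MTV voxels; when no voxel passes the
  threshold it is reported as 0 with an `empty_mtv` flag rather than
  NaN, so TLG = MTV × SUVmean stays defined (and is then 0).
* Nodal SUVmax is the maximum across regional nodes (the per-node
  alternative exists in the data; max-across-nodes is the prognostic
  covariate used here). Nodal and whole-body MTV/TLG are exact sums.

### The heterogeneity factor

For the primary tumor, the volume–threshold function V(T) is measured
at T = 40, 50, 60, 70, 80% of the lesion's SUVmax. Thresholds below
40% are excluded because the contour would admit background activity;
thresholds above 80% are excluded because the remaining volumes are
small and dominated by partial-volume effects. Exactly these five
thresholds, step 10, endpoints inclusive, are the default.

HF is the absolute slope of the OLS regression of V (cm³) on T
(percentage points): `HF = |dV/dT|`, in cm³ per percentage point.
Zero volumes at high thresholds (small tumors) are legitimate points
and are kept in the fit. Two normalization decisions deserve note:

* **Threshold axis unit.** The axis is percentage points (40–80), so a
  typical locally advanced cervical tumor scores an HF of order 1
  cm³/%, matching the magnitude scale of the cohort HF is calibrated
  to (1.072 ± 1.436). An SUV-unit axis would rescale all HFs by
  SUVmax/100; the percentage-point unit is inferred from the value
  scale of the published summaries and is the package default.
* **SUVmax for normalization** is the *measured* maximum inside the
  mask, after noise — what a scanner workstation would report. The
  phantom generator therefore snaps the default tumor center onto a
  voxel center so the profile's peak is actually sampled; without
  this, even a noise-free phantom understates SUVmax and biases every
  relative threshold.

Because thresholds are relative to SUVmax, HF is exactly invariant to a
global rescaling of all SUVs; and for a fixed normalized profile,
spatial scaling by k multiplies every V(T) by k³ and hence HF by k³.
This scaling law is the mechanism behind HF's strong rank correlation
with MTV — both are size-driven — and its independence from SUVmax when
size and peak uptake vary independently. The acceptance suite verifies
both, against the closed forms

* uniform: V(T) = (4/3)πR³ for all T ≤ 100%,
* linear radial: V(T) = (4/3)πR³(1 − T)³,
* power profile (exponent γ): V(T) = (4/3)πR³(1 − T)^(3/γ),
* necrotic core (rim fraction f): a spherical shell with
  |r/R − f| ≤ (1 − T)(1 − f).

## 2. The synthetic generators

**Phantoms.** A spherical tumor with one of five uptake profiles sits
in Gaussian background tissue (mean 1.5, SD 0.25 SUV — a mediastinal
blood-pool level — clamped at 0), with optional uniform-uptake nodal
spheres and a spherical background reference region placed in a corner
clear of all lesions. Voxel membership uses the center-of-voxel rule
(simple and convergent: the voxelized uniform-sphere volume is within
2% of (4/3)πR³ at 1 mm spacing for R ≥ 15 mm, tested). Background is
drawn first, lesion profiles overwrite their voxels, additive Gaussian
noise (if any) is applied last, then a final clamp at 0. A single seed
makes the phantom bit-reproducible. The generator does *not* model
scanner PSF/reconstruction, respiratory motion or attenuation
artifacts; passing tests therefore show the *computational* pipeline is
faithful, not that HF is robust to scanner physics.

**Cohorts.** Patients carry positive right-skewed metabolic features
drawn log-normally, moment-matched to the cohort the package emulates
(nodal SUVmax 4.1 ± 6.5, whole-body MTV 88.4 ± 106.8 cm³, HF
1.072 ± 1.436; n = 93). Event times follow a Weibull
proportional-hazards model, `h(t|x) = (κ/λ)(t/λ)^{κ−1} e^{βᵀz}`, where
z are *standardized log-features* (theoretical moments, so the linear
predictor is deterministic in the draws) — betas on raw right-skewed
features of this magnitude would produce absurd hazards. Default betas
are in the ratio 1.3 : 1 : 0.25 (0.65, 0.50, 0.125), the relative-risk
pattern of the three markers the composite score is built from.
Censoring is an administrative 120-month horizon (cf. a follow-up range
of 9–124 months) plus 30% independent uniform dropout. The baseline
scale (λ = 320 months at κ = 1) was calibrated once, by large-n
simulation at the default betas and censoring, so that ≈31% of
patients experience recurrence — the recurrence fraction of the
emulated cohort — and is not revisited. Features are drawn
independently: the synthetic calibration targets the published moments
only, not joint correlations (the HF–MTV mechanism is exercised by the
*image*-level cohort instead, where it arises physically from the
scaling law rather than by construction).

For the image-level cohort (`simulate_phantom_cohort()`), tumor size is
drawn log-normally matched to a primary-tumor MTV of 80.1 ± 96.2 cm³
(radius clamped to 8–38 mm for grid feasibility), peak SUV
independently log-normally at 14.9 ± 7.6 (clamped ≥ 3.5 so lesions stay
above the MTV threshold), with 2 mm voxels — cheap enough for a
500-patient cohort in seconds while keeping voxelization error small.

## 3. The survival stack

Kaplan–Meier, log-rank and Cox PH are thin surfaces over the
`survival` package; the tests hold them against independent oracles
(hand product-limit and O−E tabulations, a brute-force grid
maximization of the written Breslow partial likelihood, and the
identity of the log-rank statistic with the Cox score test on tie-free
data). Efron tie handling is the default — more accurate when times
have limited granularity — with Breslow available for oracle
cross-checks. Monotone likelihood (perfect separation) is reported as
an error with the offending covariate, not silently returned.

**Forward stepwise selection** adds, at each step, the candidate with
the smallest likelihood-ratio p-value below α = 0.05. The entry
criterion is a design choice: "forward stepwise" alone does not fix the
test, and the LR test at the conventional α is the least surprising
reading. The trace of every evaluated step is returned.

**Maximally selected cutpoints.** For each marker, every distinct value
whose low/high split keeps ≥10% of subjects per side is scanned; at
each cutoff the standardized log-rank statistic is computed (in
counting-process form: the cumulative sum of martingale residuals over
marker-sorted subjects, over the exact hypergeometric variance), and
the argmax is returned, with the reported cutoff the midpoint between
adjacent distinct values. The scan is tested for exact equality with an
exhaustive `survdiff` scan. The search-corrected p-value uses the
Lausen–Schumacher approximation for the supremum of the standardized
Brownian bridge over the scanned quantile range; a seeded
label-permutation p-value (default B = 1000) serves as validation, and
its null distribution is verified uniform. The 10% guard is a
degenerate-split protection chosen here; the sensitivity/specificity
reported with a cutoff classify the *binary* event indicator by
marker > cutoff, and the accompanying AUC is the binary-classifier
value (sens + spec)/2.

The published description pairs "maximization of the hazard ratio"
with the maximal-log-rank citation; the two criteria can disagree. The
log-rank form is implemented as primary (it is what the cited method
defines); an HR-maximizing variant can be emulated by scanning
`cox_fit` over the same cutoffs.

**Risk weights and groups.** Weights are Cox coefficients divided by a
reference coefficient and rounded to the nearest 0.05 (reference
exactly 1); the composite score is the weighted sum of the
dichotomized markers. Three groups are formed by recursive binary
splitting: the first cutpoint on the score, then the child with the
larger maximal statistic is split again; labels are ordered by mean
score.

## 4. Discrimination metrics

For the binary-outcome block, model scores are fitted probabilities
from logistic regressions of the event indicator (the raw-marker-sum
alternative is available by passing scores directly); for the
time-dependent block, Cox linear predictors. AUC is the Mann–Whitney
statistic with midrank ties and a Hanley–McNeil SE; paired AUCs are
compared with DeLong's test (the standard for correlated AUCs; tested
against `pROC`). IDI is the change in discrimination slope with the
two-sample SE; NRI is category-free by default (no published risk
categories exist for this setting), with the categorical variant
available.

Time-dependent AUC(t) is the cumulative/dynamic estimator: cases are
events by t, controls are subjects beyond t, with cases
inverse-probability-of-censoring weighted by 1/G(t⁻ᵢ) from the
Kaplan–Meier estimate of the censoring distribution (the constant
control weight cancels). With no censoring this reduces *exactly* to
the binary AUC of the indicator time ≤ t, which the tests assert as an
identity. iAUC averages AUC(t) over event times up to the 90th
percentile of follow-up with weights proportional to 2·f(t)·S(t)
(KM-derived event mass times survival), normalized to 1 — so a
constant-AUC marker passes through untouched, and iAUC is invariant to
strictly monotone score transforms. The default evaluation grid is
thinned to at most 50 quantile-spaced event times, with interval event
masses as weights (identical to the per-event-time jumps on the full
grid); the iAUC-difference CI is a patient-level bootstrap (percentile
95%, seeded, degenerate resamples skipped and counted, >10% skipped an
error) integrated over a window fixed from the original data.

## 5. Problem sizes, determinism and known limitations

The acceptance suite exercises: an 81³ one-millimetre phantom against
the analytic HF (within 10%; the analytic OLS value on the continuum
volumes is 0.5815 cm³/%), exact HF = 0 on a uniform phantom, the k³
scaling law (±10% voxelization tolerance), a 500-phantom cohort for the
correlation structure, hand-tabulated survival oracles, 100 replicates
of n = 2000 Weibull-PH cohorts for coefficient recovery (β̂ within ±0.1
of 0.7 in ≥95% and CI coverage in [90%, 98%]), 500 null replicates at
n = 100 for permutation-p uniformity, 20 replicates (n = 300, B = 500)
of the incremental-value simulation, and byte-identical pipeline
reruns. The incremental-value cohorts use equal betas of 0.7 per
standardized log-feature — the "three independently prognostic
markers" condition — rather than the 1.3 : 1 : 0.25 pattern, which
deliberately makes the third marker weak; sizes were chosen as a
compromise between statistical resolution and desk-scale runtimes and
are stated here as the package's own study design.

Limitations worth keeping in mind:

* At n = 93 with the default (weak) HF effect, single-cohort analyses
  are noisy: the HF cutoff, its univariate HR and even its sign in a
  stepwise fit vary across seeds (the `analysis/` drivers show one such
  draw, where dichotomized HF enters protectively). This is a property
  of small cohorts, reproduced faithfully rather than smoothed away.
* The phantom background is independent Gaussian noise; real
  mediastinal background is spatially correlated, so the background
  mean + 2 SD threshold is better behaved here than on real scanners.
* The Lausen–Schumacher corrected p is mildly conservative at moderate
  n; the permutation option is exact up to Monte-Carlo error.
* HF here is the volume-threshold slope only; texture-matrix indices
  (GLCM entropy and kin) and nodal HF are out of scope.
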