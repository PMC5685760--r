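# hfpet

Intratumoral metabolic heterogeneity and prognostic modelling for
FDG-PET.

## What this is for

On pre-treatment ¹⁸F-FDG PET/CT, a tumor's uptake pattern carries
prognostic information beyond the classical metabolic parameters. The
classical parameters are:

- **SUVmax** — the peak standardized uptake value of a lesion,
  `SUV = activity concentration (MBq/g) / (injected dose [MBq] / body weight [g])`;
- **MTV** (metabolic tumor volume, cm³) — the volume of lesion voxels
  whose SUV exceeds an isocontour threshold, here the mediastinal
  background mean + 2 SD;
- **TLG** (total lesion glycolysis) — `MTV × SUVmean`;
- whole-body MTV/TLG — primary tumor plus the sum over regional nodes.

The **heterogeneity factor (HF)** summarizes how quickly the lesion's
isocontour volume collapses as the relative threshold rises: with
volumes V(T) measured at T = 40, 50, 60, 70, 80% of SUVmax (below 40%
the contour admits background, above 80% partial-volume effects
dominate), HF is the absolute slope `|dV/dT|` of the ordinary
least-squares line of V on T, in cm³ per percentage point. A perfectly
uniform lesion has HF = 0; a lesion whose uptake falls off steeply from
a hot core loses volume fast and scores high.

`hfpet` implements, as tested reusable R code:

- synthetic PET phantoms (spherical tumors with uniform, linear, power,
  necrotic-core and multifocal uptake profiles, plus nodes, background
  tissue and noise) and closed-form volume-threshold oracles;
- simulated survival cohorts under a Weibull proportional-hazards model
  with log-normal metabolic features;
- feature extraction: SUV computation, background-derived MTV
  thresholds, per-lesion SUVmax/SUVmean/MTV/TLG, nodal and whole-body
  aggregation, and the HF;
- the survival stack: Kaplan–Meier, log-rank, Cox PH (via the
  `survival` package) with forward stepwise selection, maximally
  selected log-rank cutpoints (Contal–O'Quigley) with a
  Brownian-bridge-corrected or permutation p-value, Cox-coefficient
  risk weights and recursive risk grouping;
- discrimination metrics: ROC AUC with DeLong paired comparisons, IDI,
  NRI, cumulative/dynamic time-dependent ROC with IPCW, integrated AUC
  and bootstrap CIs for iAUC differences;
- a deterministic end-to-end pipeline (`run_pipeline()`) emitting the
  full set of numeric report tables.

Everything runs on synthetic data generated in code; no clinical data
ship with the package.

## Worked example

Measure the HF of a phantom with a linear radial uptake profile
(R = 30 mm, 1 mm voxels) and compare with the continuum truth
V(T) = (4/3)πR³(1 − T)³:

```r
library(hfpet)
sp <- phantom_spec(grid_shape = c(81, 81, 81), tumor_radius_mm = 30,
                   profile = "radial_linear", suv_max_target = 10, seed = 1)
ph <- generate_phantom(sp)
curve <- volume_threshold_curve(ph$volume, role_mask(ph$lesions, "primary"))
cbind(curve, analytic = analytic_volume_threshold("radial_linear", 30)$volume_cm3)
#>   threshold_pct volume_cm3   analytic
#> 1            40     24.405 24.4290245
#> 2            50     14.147 14.1371669
#> 3            60      7.153  7.2382295
#> 4            70      3.071  3.0536281
#> 5            80      0.925  0.9047787
fit_hf(curve)$hf
#> [1] 0.58036      # cm^3 per % point; the analytic value is 0.58132
```

The measured volumes sit within ~2% of the closed form and the HF
within 0.2%. A uniform sphere of any size gives a flat curve and
HF = 0, and doubling the radius multiplies HF by 2³ — HF is a
size-coupled heterogeneity measure, which is why it correlates strongly
with MTV but not with SUVmax across a cohort (run
`analysis/02_phantom_cohort_correlations.R`: Spearman rho = 0.93 vs
0.07 at n = 500).

The cohort-level analysis is driven by the numbered scripts under
`analysis/` (simulate phantoms → image-cohort correlations → survival
models → discrimination/risk groups); each writes its tables under
`results/`.

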