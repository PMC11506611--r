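# calfmfi

Quantification of lower-extremity fat distribution and muscle fat
infiltration (MFI) from axial T2-weighted MR image stacks — as a tested,
fully synthetic-data-driven R pipeline.

## The problem

On T2-weighted images of the calf, fat is bright and lean muscle dark.
Three quantities summarize lower-leg fat distribution in aging and
metabolic-health research:

* **SFT** (mm) — subcutaneous fat thickness of the annulus under the skin.
  Per slice, `SFT = 2A / (L1 + L2)`: the annulus area over the mean of its
  inner and outer boundary lengths, averaged over the central seven slices
  of a nine-slice stack.
* **BMA** (mm²) — fibula bone-marrow cross-sectional area.
* **MFI indexes** — features of the normalized muscle-ROI pixel-intensity
  histogram (integral fixed at 100): its raw mean, the mode and full width
  at half height of a fitted lineshape, and Pearson skewness
  `(mean − mode)/sd`. The fitted lineshape is a pseudo-Gaussian
  `y = h·exp(−4 ln2 (x−x₀)²/FWHM(x)²)` with `FWHM(x) = a + b·x`, reducing to
  a Gaussian at `b = 0`.

Subjects are graded into four MFI severity groups (normal / mild / moderate
/ severe) by Fuzzy C-Means on the PCA-selected top-two features (mean and
mode intensity), with the cluster count chosen by linear separability of
the candidate solutions. A statistical battery then relates SFT, BMA and
MFI to age, BMI, sex and obesity.

Because the underlying clinical images cannot be redistributed, the package
includes a phantom generator that rasterizes synthetic calf slices with
planted ground truth (annulus thickness, marrow area, muscle fat fraction,
severity mixture, association slopes, bias field, noise) and a cohort
sampler that reproduces the emulated study population: 107 subjects
(64 M / 43 F), SFT 4.3 ± 2.2 mm (M) / 8.9 ± 3.7 mm (F), BMA
35.7 ± 21.1 mm² (M) / 32.6 ± 20.0 mm² (F), severity mixture
42 / 42 / 14 / 2 %.

## Worked example

```r
library(calfmfi)

# one synthetic subject: 9 slices, planted 8.9 mm annulus, 35 mm^2 marrow,
# 15% muscle fat fraction
truth <- subject_truth("S001", sex = "F", age = 50, bmi = 30,
                       true_sft = 8.9, true_bma = 35,
                       true_fat_fraction = 0.15, severity_class = "mild",
                       seed = 7L)
stack <- generate_subject(truth, phantom_spec())
res <- process_subject(stack)   # bias correction + morphometry + histogram
c(sft = res$sft$sft, bma = res$bma$bma,
  mfi_mean = res$features$mean_intensity,
  mfi_mode = res$features$mode_intensity)
#>       sft        bma   mfi_mean   mfi_mode
#>  8.878069  35.350000 143.595034 114.600000
```

The measured SFT (8.88 mm) recovers the planted 8.9 mm within rasterization
error; the MFI mean of ≈ 144 a.u. sits above the lean-muscle intensity
(100 a.u.) by 300 × the planted fat fraction, as the intensity model
implies.

The cohort-level analysis is organized as numbered drivers under
`analysis/` (simulate → measure → cluster → repeatability → associations),
writing their tables to `results/`. On the default 107-subject cohort they
print, among other things:

```
SFT: F 9.1 +/- 3.6 vs M 4.7 +/- 2.0 — t = 8.17, p = 7.37e-13
BMA: F 33.4 +/- 18.0 vs M 39.1 +/- 18.3 — t = -1.59, p = 0.116

Cluster-count diagnostics (largest separable candidate wins):
 c          J separable
 3 18.9840726      TRUE
 4  1.2301012      TRUE
 5  0.8493321     FALSE

Severity groups:
  normal      45 (42.1%)
  mild        45 (42.1%)
  moderate    15 (14.0%)
  severe       2 ( 1.9%)
```

— the sex difference in SFT (about twofold, strongly significant) against
none in BMA, the choice of four severity groups (3 and 4 separable, 5 not),
and exact recovery of the planted severity mixture. The association stage
reproduces the planted sex-specific pattern (SFT falls with age in males
only, rises with BMI in females only; BMA rises with age in females and
with BMI in males) and finds zero significance flips when measured
segmentation repeatability is injected as noise.

## Package layout

* `R/` — phantom generator, bias correction, morphometry, histogram/MFI
  features, severity clustering, association statistics, pipeline
  orchestration (`run_pipeline()` runs the whole chain from one config).
* `analysis/` — the numbered narrative drivers.
* `vignettes/calfmfi-methods.Rmd` — the model, its assumptions, parameter
  choices, numerical decisions and limitations.
* `tests/testthat/` — unit, property and cohort-recovery suites.
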