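---
title: "Quantifying lower-extremity fat distribution and muscle fat infiltration: methods"
author: "calfmfi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lower-extremity fat distribution and muscle fat infiltration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement problem

On axial T2-weighted MR images of the calf, fat is bright and lean muscle is
dark. Three quantities summarize how fat is distributed in the lower leg:

* **SFT** — subcutaneous fat thickness: the average thickness of the fat
  annulus under the skin, in mm;
* **BMA** — the cross-sectional area of the fibula bone-marrow cavity, in
  mm²;
* **MFI** — muscle fat infiltration, indexed not by segmenting individual
  fat streaks (unreliable at partial-volume scales) but by the shape of the
  pixel-intensity histogram of a muscle region of interest: as infiltration
  progresses, the histogram's mean, mode and width all move up.

`calfmfi` implements this measurement chain end to end and, because clinical
images cannot be redistributed, ships a synthetic phantom generator that
plants every quantity the chain is supposed to recover. All package
development and testing runs against phantoms whose ground truth is known
exactly.

## The phantom generator

`phantom_spec()` describes one subject's geometry and signal model. A slice
is built from five regions: background, an elliptical muscle compartment, a
subcutaneous annulus, and the fibula as a cortical ring around a marrow
disk. Two properties are exact by construction and matter downstream:

* the subcutaneous annulus is a **constant normal-thickness offset band**
  around the compartment (computed from the exact point-to-ellipse
  distance), so the planted thickness is the analytic truth the SFT formula
  must recover — for parallel convex curves, `2A/(L1+L2)` equals the offset
  thickness identically;
* marbling is a **thresholded smooth Gaussian random field** on the muscle
  pixels, with the threshold chosen per slice by exact count, so the planted
  clumped fat fraction is hit exactly before any blurring.

Signal intensities are arbitrary units with fat : muscle : cortical bone :
background = 400 : 100 : 20 : 5. Only the ordering (fat well above muscle)
matters for the histogram analysis; the 4:1 fat-to-muscle contrast is
typical of T2-weighted turbo-spin-echo at high field.

Two realism components were deliberate design choices:

* `diffuse_fraction` (default 0.3) routes part of the planted fat fraction
  into a homogeneous intensity shift of every muscle pixel, emulating
  sub-voxel (intramyocellular and fine extramyocellular) lipid that no
  0.7 mm voxel resolves. Without it the histogram mode stays pinned at the
  lean-muscle peak no matter how much marbling is planted, and the
  mean/mode/width trio would not rise together with severity the way real
  infiltration profiles do.
* `partial_volume_mm` (default 0.7 mm, one pixel) blurs the marbling
  indicator before compositing, creating the intermediate intensities that
  finite resolution produces at patch boundaries. The blur is applied to the
  fat-content map only, so tissue boundaries and the truth masks remain
  crisp, and a phantom with zero fat fraction has exactly lean-intensity
  muscle.

Degradations follow the standard MR model: a smooth multiplicative bias
field (random low-order polynomial pattern, fractional amplitude 0.2 by
default) and additive Gaussian noise (sd 8 a.u. against muscle at 100,
an SNR ≈ 12 typical of the acquisition emulated). A Rician noise switch
exists; at this SNR the difference is immaterial for histogram features.
Slice-to-slice geometry varies smoothly by ≤ 3 % in the compartment radii
while the planted annulus thickness and marrow area stay fixed, so the
central-seven-slice averages remain meaningful estimates of the truth.

## The cohort generator

`cohort_config()` defaults encode the emulated study population: 64 males
and 43 females; male age 57.9 ± 17.8 y, female 52.7 ± 14.6 y; male BMI
28.4 ± 4.4, female 30.3 ± 5.7; SFT 4.3 ± 2.2 mm (M) and 8.9 ± 3.7 mm (F),
truncated at 1 mm; marrow area 35.7 ± 21.1 mm² (M) and 32.6 ± 20.0 mm² (F),
truncated at 4 mm²; and a four-level severity mixture at proportions
0.42 / 0.42 / 0.14 / 0.02 with planted per-class muscle fat fractions
0.05 / 0.15 / 0.30 / 0.60.

Three sampling choices are worth spelling out:

* **Quantile-stratified draws** (default): each per-sex marginal is drawn as
  a random permutation of truncated-normal quantiles, so a finite cohort's
  sample moments match the configured distribution closely; `sampling =
  "random"` restores iid draws. The package emulates a *specific printed
  cohort*, and stratified sampling keeps a 43-subject cohort's mean from
  wandering a whole standard error away from the population it is supposed
  to represent.
* **Quota severity allocation** (default): largest-remainder allocation of
  the mixture over the cohort, which at n = 107 gives exactly 45/45/15/2;
  `severity_allocation = "multinomial"` restores random draws.
* **Planted slopes** are applied to mean-centered covariates with the
  residual spread reduced so each marginal keeps its stated total sd. The
  defaults plant the sex-specific association pattern of the emulated
  cohort: SFT falls with age in males and rises with BMI in females; marrow
  area rises with age (strongly in females) and with BMI in males. The MFI
  slopes default to zero so that per-class fat fractions are exactly the
  four planted levels; association tests that need a planted MFI trend set
  them explicitly. Note that no MFI–BMA link is planted by default: the
  phantom cohort is a recovery instrument, not a causal model of the
  marrow–muscle relationship.

Truncation is honest about its consequences: drawing SFT from a normal
truncated at 1 mm raises the male cohort mean by ≈ 0.3 mm above the nominal
4.3 mm, and the BMA floor at 4 mm² raises the male mean by ≈ 2.9 mm². These
shifts are properties of the planted distributions, not bugs, and the
recovery checks account for them by using ±2 standard-error bands.

## Bias correction

The default estimator fits a low-order (3) 2D polynomial to log-intensities
over a tissue mask and exponentiates, normalized to mean 1 over the mask so
correction preserves mean tissue intensity. The estimation mask in the
pipeline is the muscle compartment: it is the tissue whose histogram is
analyzed, and marbling (correlation length ≈ 2.5 mm) is far too fine for a
degree-3 polynomial across a ≈ 90 mm leg to absorb. An `"n4"` method
delegates to SimpleITK's N4 through the system `python` when available; the
polynomial method is the default because it is self-contained, fast and
exactly testable, and on smooth planted fields the two agree.

## Morphometry

Per slice, `SFT_i = 2 A_i / (L1 + L2)_i` with the area from the pixel count
and the boundary lengths from sub-pixel iso-contours: the binary mask is
lightly Gaussian-smoothed (σ = 1.5 px) and traced at the 0.5 level with
marching squares. Pixel-edge perimeters overestimate lengths by up to ~27 %
(they measure the staircase, not the curve) and would bias SFT low by the
same mechanism; the smoothed-contour lengths are within ~1 % for circles of
the relevant radii, with the worst case ≈ 3 % for a 1 mm-thin annulus. The
annulus is traced as two solid shapes — the hole-filled outer boundary and
the hole itself — so thin annuli survive the smoothing. The subject value
averages slices 2–8 of 9 (the central seven; the outermost slices of a real
acquisition sit in the coil's inhomogeneous fringe). BMA uses the same
central-seven convention, chosen for symmetry with SFT.

The muscle ROI is the muscle mask strictly inferior to a horizontal line
through the fibula centroid (centroid row of cortex + marrow, rounded
half-down). "Centroid of the full fibula mask" is this package's precise
reading of dividing the fibula "from its center"; the alternative readings
(marrow-only centroid, bounding-box center) differ by under a pixel on
phantom geometry.

`perturb_mask()` emulates manual-redraw variability for repeatability
studies: the mask boundary moves by a smooth random field applied through
the signed distance transform, so the displacement sd is exactly the
requested magnitude in pixels, and topology changes trigger a retry.

## Histogram profile and lineshape fitting

ROI intensities from the corrected central seven slices are binned on a
shared grid (default width 2 a.u., ≈ 200 bins over the phantom's range; the
emulated workflow does not state a binning, and features are stable within
2 % under halving), averaged pointwise, and normalized so the trapezoidal
integral is exactly 100 — profiles from different subjects are then directly
comparable.

The fitted model is the pseudo-Gaussian

y(x) = h · exp( −4 ln 2 · (x − x₀)² / FWHM(x)² ),  FWHM(x) = a + b·x,

which reduces to a Gaussian at b = 0. The intensity-dependent width inside
the standard 4 ln 2 FWHM kernel is the conventional pseudo-Gaussian
construction for right-tailed peaks. Fitting is bounded Levenberg–Marquardt
with deterministic initialization (argmax, raw FWHM, b = 0); the
pseudo-Gaussian fit starts from the fitted Gaussian solution, which makes
the nested-model residual ordering (pseudo ≤ Gaussian) hold by
construction. Non-convergence flags the result instead of throwing, and a
pseudo-Gaussian fit that fails falls back to the nested Gaussian optimum.

Features: mean and sd are moments of the **raw** normalized profile; the
mode is the argmax of the **fitted** curve on a 10×-refined grid; FWHM is
measured numerically on the fitted curve; skewness is Pearson's
(mean − mode)/sd. Whether the emulated workflow took mean/sd from the raw
profile or the fitted curve is ambiguous; raw is this package's primary
convention and `moments = "fitted"` exposes the alternative (on phantom
profiles the two agree to well under a bin).

## Severity clustering

Features (mean, mode, FWHM) are z-scored; PCA (via the eigendecomposition
of the correlation matrix, loadings sign-fixed for determinism) ranks
features by the sum of absolute loadings over the components needed for
95 % variance, and the top two go to clustering. On phantom cohorts one
component suffices and the selection is mean + mode. Two quirks of this
importance rule are documented rather than patched: with exactly duplicated
features plus an independent one, the rule can rank the independent feature
highest (its loading concentrates in its own late component); and svd-based
PCA returns an arbitrary basis when eigenvalues tie, which is why the
implementation eigendecomposes the correlation matrix instead.

Fuzzy C-Means runs the standard alternating updates (fuzzifier m = 2,
tolerance 1e-5 on memberships, ≤ 1000 iterations, best of 10 seeded
restarts by objective; a point coinciding with a centroid takes full
membership there). Hard labels are maximum membership; clusters are renamed
normal / mild / moderate / severe in ascending centroid mean-intensity
order, with the mode coordinate breaking ties.

**Cluster-count selection and the separability margin.** The selection rule
keeps the largest candidate count (of 3/4/5) whose hard-label solution is
linearly separable — because the objective falls with the count, that is
also the separable solution with the lowest objective. A subtlety makes the
unqualified rule vacuous: maximum-membership labels from FCM form a
nearest-centroid (Voronoi) partition, and any two Voronoi cells are
separable by their bisector with margin zero, so *every* candidate would
pass a pure feasibility test. The package therefore requires the convex
hulls of two clusters to be disjoint *and* separated by a resolvable gap
(default 0.1 of the pooled per-coordinate sd; `margin = 0` restores pure
feasibility). Genuine cluster structure leaves a gap; an over-split cluster
does not. On phantom cohorts this reproduces the expected pattern: 3 and 4
clusters separable, 5 not, hence 4 chosen. The raw objective values are
dataset-specific (they scale with n and the feature units) and are reported,
not matched to any external value.

## Association battery

Two-sample comparisons use the pooled-variance t-test (the default of the
emulated workflow's tooling; Welch is deliberately not silently
substituted). Correlations are Pearson with the exact t-based two-sided p;
multivariate fits are OLS on age + BMI with the overall F-test as the
primary p (per-coefficient p values are also reported, since "multivariate
correlation p" is ambiguous). The battery crosses four outcomes (SFT, BMA,
MFI mean, MFI mode) with age and BMI plus the MFI-vs-BMA and MFI-vs-SFT
correlations over nine strata (all, by sex, by obesity at the BMI ≥ 30
cutoff, sex × obesity). **No multiple-testing correction is applied** — all
144 p values are raw, matching the emulated analysis; treat the battery as
descriptive, not confirmatory.

Robustness: each measurement column is perturbed by zero-mean Gaussian noise
with sd equal to its repeatability CV times the value, the battery is
recomputed 10 times, p values are averaged, and rows whose significance call
flips are flagged. The CVs default to the repeatability of manual
segmentation this pipeline emulates (3.0 / 3.4 / 3.2 / 4.1 % for SFT / BMA /
MFI mean / MFI mode) and can be replaced by measured ones
(`analysis/04_repeatability.R`).

## Numerical choices and degenerate inputs

* Seeds: every stage and subject derives its stream from a master seed via
  a 31-bit label hash; identical configurations are byte-deterministic, and
  subject ids are folded into the stream so equal-seeded subjects differ.
* Bias estimation refuses masks under 50 pixels; annulus tracing refuses
  masks that are not one component with one hole, naming the defect;
  an empty marrow mask on any slice is an error; an empty muscle ROI is a
  warning (the result is returned) because a cohort run must not die on one
  degenerate phantom — `run_pipeline()` additionally excludes failing
  subjects with a recorded reason.
* Histograms get one empty guard bin on each side so a single-occupied-bin
  profile still has a well-defined trapezoidal integral.
* FWHM(x) is clamped positive inside the fit kernel; fits are bounded
  (h > 0, a > 0, |b| ≤ 2).
* Problem sizes in tests and recovery checks: 256² pixels × 9 slices per
  subject, cohorts of 43/64/107 subjects — the full emulated cohort at the
  full emulated resolution, chosen so each recovery check completes in a
  couple of minutes on one CPU.

## What the phantom does and does not establish

Passing recovery checks on phantoms establishes that the measurement chain
is unbiased at realistic contrast, noise, inhomogeneity and partial-volume
scales, and that the clustering and statistics recover planted structure at
the cohort's size. The phantom does **not** model real anatomy's
non-elliptical leg sections, fascia, vessels, tibia, through-plane leg
curvature, coil-specific bias-field shapes, pulse-sequence physics, or any
physiologic MFI–BMA coupling; conclusions about real cohorts require real
images. The severity mixture's severe class has n = 2 by design — its
recovery is all-or-nothing and its group profile is an average of two
subjects, exactly as fragile as in the emulated cohort.
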