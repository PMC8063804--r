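---
title: "Detecting spleen lacerations from CT: models, features, and phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spleen lacerations from CT: models, features, and phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Splenic laceration is among the most common injuries in blunt abdominal
trauma. On contrast-enhanced CT a laceration appears as a linear or
branching hypodense region extending from the capsular surface, typically
disrupting the otherwise smooth splenic contour. `splenometrics`
implements an automated detector for this pattern: given an abdominal CT
volume and a binary spleen segmentation, it quantifies the texture of the
parenchyma and the irregularity of the contour, and classifies the sample
as healthy or lacerated with classical machine-learning models.

The pipeline has five stages:

1. **I/O and QC** — volumes (NIfTI or DICOM series) and masks are loaded
   with their physical spacing; masks whose segmented volume falls below a
   threshold (default 80 cm³ — far below any plausible spleen) are treated
   as segmentation failures and removed.
2. **Texture features** — per axial slice, histogram statistics of the
   masked intensities (mean, variance, skewness, kurtosis, Rényi entropy)
   and responses of a 40-filter Gabor bank (5 scales × 8 orientations;
   local energy and mean amplitude per filter).
3. **Geometry features** — per axial slice, box-counting fractal
   dimensions of the segmentation boundary and of the filled segmentation,
   plus circularity (`4πA/P²`), eccentricity, orientation, and the
   convex-area difference.
4. **Aggregation** — per-slice features are summarized across slices by
   mean, standard deviation, and maximum into one fixed-order vector per
   sample (276 features with the defaults).
5. **Classification** — random forest, Gaussian naive Bayes, RBF SVM, a
   random-subspace k-NN ensemble, and a random-subspace LDA ensemble,
   under a stratified 80/20 train/test split with stratified 5-fold
   cross-validation on the training portion, per-grade accuracy, and a
   leave-one-site-out analysis.

Because clinical trauma CT collections are access-restricted, the package
ships a phantom generator that emulates the geometry of the task; the
whole pipeline is exercised and tested on those synthetic cohorts.

## Feature models and their parameters

### Histogram statistics

Intensities inside the mask on each slice are summarized by population
central moments (skewness `m₃/m₂^1.5`, excess kurtosis `m₄/m₂² − 3`; both
reported as 0 when the variance is 0) and by the Rényi entropy

H_α = log(Σᵢ pᵢ^α) / (1 − α)   (nats),

computed over an `n_bins` histogram with zero-count bins dropped. At
`α = 1` the Shannon limit `−Σ pᵢ log pᵢ` is returned. Defaults: `α = 2`
(collision entropy — a standard, variance-friendly choice when the order
is not otherwise dictated) and 64 bins over a fixed abdominal window of
[−150, 250] HU, so that histograms are comparable across samples; a
per-sample min/max window is available (`intensity_range = NULL`), in
which case the entropy becomes invariant under affine intensity maps.
Values outside the window are clamped into the edge bins rather than
dropped, so no voxel silently disappears.

### Gabor bank

Each filter is a Gaussian envelope modulated by a complex plane wave,

g(x, y) = exp(−(x′² + γ²y′²)/(2σ²)) · exp(i(2πx′/λ + ψ)),

with `x′ = x cos θ + y sin θ`, `y′ = −x sin θ + y cos θ`. The bank uses 5
scales × 8 orientations (`θ_k = kπ/8`), wavelengths in a geometric
progression `λ_s = 4·√2^s` pixels, `σ = 0.56λ` (≈ one octave bandwidth),
aspect ratio `γ = 0.5`, phase `ψ = 0`, truncated at ±3σ. These are the
standard parameterization choices for texture banks of this layout.
The slice is cropped to the mask bounding box, the background zeroed, and
the complex convolution evaluated by zero-padded FFT. From each response
magnitude we take the local energy (sum of squares) and mean amplitude
(sum of magnitudes) over the masked support. By default both are divided
by the masked-pixel count: a raw sum scales with region size, conflating
texture with spleen cross-section; the raw behavior is available via
`gabor_normalize = FALSE`.

### Box-counting fractal dimension

`N(r)` counts origin-anchored `r × r` boxes containing at least one
positive pixel; the dimension is the negative slope of the OLS fit of
`log N(r)` on `log r`. Numerical choices that matter:

* **Scales** are the dyadic progression `1, 2, 4, …, 512` (capped at the
  image size). Scales uniform in `log r` weight each octave equally;
  an arithmetic sequence of sides places almost all fit points in the
  coarse regime where `N` is small and step-like, which biases the slope
  substantially (a one-pixel straight line fits near 0.85 instead of 1).
* **Exclusions**: `N(r) = 0` (nothing to cover) and the saturated
  `N(r) ≤ 1` tail, which is flat and carries no scaling information.
  Fewer than 3 surviving scales is an error, surfaced per slice.
* **Variants**: `df_perimeter` uses the one-pixel 8-connected boundary
  raster; `df_area` uses the filled mask, with scales additionally capped
  at a quarter of the smaller bounding-box extent because at box sides
  comparable to the region the count is dominated by the boundary term
  (`∝ P/r`) rather than the area term (`∝ A/r²`), deflating the slope of
  genuinely 2D regions.
* The grid is anchored at the image origin with no offset averaging, so
  results are exactly reproducible; translation experiments in the test
  suite bound the anchoring sensitivity at ±0.05.

### Shape descriptors

Circularity uses the pixel-count area and a perimeter obtained by
Moore-neighbor boundary tracing with the Vossepoel–Smeulders
corner-corrected step weights (0.980 per axial step, 1.406 per diagonal,
−0.091 per corner). Raw boundary-pixel counting systematically
overestimates the perimeter of smooth digital curves and would bias
circularity low by ~10%; with the corrected polygonal length, rasterized
disks of radius ≥ 25 px measure within a few percent of 1. Eccentricity
and orientation come from the second-moment equivalent ellipse (with the
1/12 pixel-variance term), orientation in degrees in (−90°, 90°] with the
y-axis pointing up. The convex-area difference is the convex hull area of
the pixel centers minus the pixel count, clamped at zero — effectively 0
for convex regions and close to the notch area for notched ones.

### Aggregation

Per-slice values are aggregated by mean, SD, and max across all slices
with ≥ 32 foreground pixels (`min_pixels`; smaller cross-sections near the
organ poles give degenerate shape and fractal estimates). Summary
statistics are the least-assuming way to turn per-frame features into one
volume-level vector. Features are deliberately *not* standardized at
extraction: z-scoring is fit inside each training fold only, so no test
information leaks into the scaler.

## Classification protocol

The positive class is *lacerated* throughout. The 80/20 split and the
5-fold CV folds are stratified by label (and by AIS grade bin where counts
permit) with largest-remainder allocation, so the class ratio in every
partition is preserved within one sample. Model defaults, chosen to
mirror the common defaults of the classical toolbox family this model
list comes from (none are tuned): random forest with 500 trees and √p
candidate features per split; Gaussian naive Bayes (features that are
constant within a class are dropped, as their Gaussian likelihood
degenerates); RBF SVM with C = 1 on z-scored features; k-NN ensemble =
random-subspace ensemble of 30 learners, k = 5, subspace fraction 0.5;
subspace-discriminant = 30 LDA learners on random subspaces of fraction
0.5 (capped below the training-set size; learners whose within-class
covariance is singular are skipped). AUC is computed from each model's
continuous score (vote fraction, posterior, or probability) by the
Mann–Whitney rank statistic with midranks for ties; the test suite
cross-checks it against trapezoidal ROC integration and an independent
ROC implementation. Per-grade accuracy is reported over the bins
{healthy, AIS 2, AIS 3, AIS 4∪5}; empty bins are omitted rather than
reported as zero. The leave-one-site-out analysis trains on all samples
of one site and evaluates on the other, optionally subsampling the test
site stratified by grade.

Every stochastic step takes an explicit seed, and every report embeds a
provenance stamp (package version, seed, MD5 of the resolved YAML
config), so all numbers are reproducible bit for bit.

## What the phantoms emulate — and what they do not

Each phantom is an ellipsoidal "spleen" (volume drawn from a physiologic
160–320 cm³ band, anisotropic semi-axes, random in-plane rotation) with a
smooth low-amplitude boundary undulation, homogeneous parenchyma
(sample-level intensity ~N(100, 15) HU-equivalents), voxel Gaussian noise
(SD 12 HU), and a structured background, on an axial grid of 64 slices of
5 mm at 0.8 mm in-plane (256×256 by default; 512×512 available — the
256 grid keeps a 99-sample cohort run in minutes while leaving the
feature definitions unchanged, since wavelengths and box sides are in
pixels). Lacerated phantoms add three severity-scaled channels:
band-limited radial boundary roughening (frequencies 8–16), one to three
wedge notches, and a hypodense track crossing the capsular surface
(branching at higher grades) — the mask follows the disrupted contour and
stays a single connected component. Severity parameters are strictly
monotone in AIS grade, with grade 2 chosen close enough to the healthy
undulation band that mild cases are genuinely harder, mirroring the
clinical observation that misclassifications concentrate in mild and
moderate injuries. Site B carries a +10 HU offset and ×1.2 noise SD, a
plausible scanner-protocol shift.

The default cohort is 54 healthy + 45 lacerated with grade counts
15/16/10/4, and 6 deliberately undersized healthy masks so the QC filter
has real failures to catch (99 → 93 samples).

What the phantoms do **not** contain: real parenchymal texture,
hematomas or active hemorrhage, neighboring-organ confounders, partial
volume and beam-hardening artifacts, or segmentation errors other than
gross undersizing. A passing test suite therefore demonstrates that the
implementation is correct and that the method recovers a contour/texture
signal it is designed for — not that the reported performance transfers
to clinical CT.

## Degenerate inputs and tie-breaks

* Empty intensity sets, empty mask slices, and empty seeds are errors;
  samples whose every slice is unusable go to an explicit exclusion
  report, never silently dropped.
* Dice of two empty masks is defined as 1 (and logged).
* Constant intensities: variance 0, skewness/kurtosis reported 0,
  entropy 0.
* All-equal scores give AUC 0.5; a test set without positives yields
  sensitivity `NA` with a message, never a silent 0.
* Orientation of a moment-isotropic region is reported as 0°.

## Known limitations

* The optional mask-refinement stage is a plain region-based
  morphological contour evolution with periodic reinitialization; it is a
  convenience for phantom experiments, not a substitute for a trained
  spleen segmenter, and precomputed masks are the intended input.
* Box-counting on a 2D slice treats each frame independently; no 3D
  box counting or multifractal spectrum is computed.
* The DICOM reader supports uncompressed little-endian single-frame CT
  series only.
* Gabor features use response magnitudes; phase information is discarded.

## Reproducing a run

```{r}
library(splenometrics)
config <- default_run_config(seed = 1)
res <- run_pipeline(config, out_dir = "artifacts")
res$test$metrics
```

The same stages are available individually (`generate_cohort()`,
`qc_filter()`, `build_feature_table()`, `split_train_test()`,
`cross_validate()`, `evaluate()`, `leave_one_site_out()`) and through the
`exec/splenometrics` command-line wrapper.
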