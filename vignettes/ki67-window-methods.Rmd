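---
title: "Methods: automated Ki67 scoring and window-trial response statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated Ki67 scoring and window-trial response statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ki67window)
```

# The scientific problem

Presurgical ("window") trials in ER+ breast cancer treat patients for a few
weeks between diagnostic biopsy and surgery and read out response as the
change in the Ki67 proliferation index — the percentage of tumor nuclei
staining positive for Ki67 by immunohistochemistry (IHC), scored in a 1 mm²
hotspot. Manual scoring is subject to inter-observer variability, so an
automated scorer is validated against visual counts and then applied to the
paired pre/post slides; the paired indices feed nonparametric response
statistics, and gene-expression proliferation signatures provide an
orthogonal readout. This package implements that full computational chain
and a synthetic-data generator that makes every stage testable end to end
without any external images or arrays.

# Automated IHC scoring

## Stain model

Synthetic slides and stain separation share one two-chromogen Beer–Lambert
model: per pixel, transmitted light is
$I_c = I^0_c \, 10^{-(a_H v_{H,c} + a_D v_{D,c})}$
for channels $c \in \{R,G,B\}$, with the standard H-DAB unit vectors
$v_H = (0.65, 0.70, 0.29)$ (hematoxylin, blue) and
$v_D = (0.27, 0.57, 0.78)$ (DAB, brown), normalised to unit length in
optical-density (OD) space. `stain_deconvolve()` inverts the model by least
squares, so stain separation is exactly well-posed on generated slides and
standard (Ruifrok-style colour deconvolution) on real RGB input.

## The scoring chain

1. **Sliding window.** An 80 × 80 px window at 10 px stride covers the
   image (`patch_grid()`); anchors are 0-based, row-major, top-left, and
   every window lies fully inside the image, giving
   $\lfloor (d - 80)/10 \rfloor + 1$ anchors per axis. The same grid serves
   training-patch extraction and inference.
2. **Patch classification.** Each window receives a probability that a
   nucleus sits at its center. The default backend is a ridge-penalised
   logistic regression (fixed $\lambda = 0.03$) on window summaries: mean
   hematoxylin amount, mean DAB amount and mean brightness over the full
   window and over centered 20 px and 10 px boxes, the brightness SD, the
   center-minus-window contrasts, and the offset of the stain-mass centroid
   from the window center. All features are box sums, so the whole map is
   computed from summed-area tables of the deconvolved image; the per-patch
   and whole-image paths agree to machine precision (tested). The backend is
   a pluggable contract — any model exposing `predict_probability()` in
   [0, 1], such as a convolutional network, can stand behind it; none ships
   here because the architecture adds nothing testable at desk scale.
3. **Probability map → nucleus map.** The per-anchor probabilities form a
   stride-resolution map; a separable discrete Gaussian with reflecting
   boundaries (`smooth_to_nucleus_map()`) yields the nucleus map. Default
   sigma is `expected_radius_px / (2 * stride_px)` grid units.
4. **Peak extraction.** Every interior cell above the detection threshold
   (default 0.25) is a candidate; candidates are refined to sub-grid
   precision by a separable quadratic fit and reduced by greedy non-maximum
   suppression at 15 px. Greedy suppression rather than a plain
   8-neighbourhood local-maximum test matters: two nuclei ~2 grid cells
   apart often form a monotone ridge on the 10 px map in which one peak
   swallows the other; suppression over all above-threshold cells recovers
   both (measured recall rose from ~0.55 to ~0.97 on the default panel).
5. **Contours.** Each kept peak is expanded to a closed polygon by casting
   16 radial rays on the *total stain OD image* and stopping where the
   density first falls below 50% of the per-nucleus peak, clipped at
   1.8 × the expected radius. The level set is taken on the image rather
   than the nucleus map because nucleus radii (~7 px) are below the 10 px
   grid resolution; the map localises, the image delineates.
6. **Positivity.** Pixels inside the (star-shaped) contour are
   stain-separated; a nucleus is Ki67-positive iff its mean DAB amount
   exceeds `dab_threshold` (default 0.2 OD) *and* its mean brightness stays
   below `brightness_threshold` (default 0.8), the brightness gate excluding
   unstained bright debris. Contours under 3 px are flagged invalid and
   excluded from all counts. The thresholds were calibrated once on held-out
   synthetic calibration slides and frozen; on the default panel the
   per-nucleus positivity accuracy against ground truth is ≥ 0.95 (tested).
7. **ROI score and hotspot.** `score_roi()` runs the chain on the ROI plus
   a one-window margin and counts only calls whose centers fall in the
   half-open rectangle; `n_positive + n_negative = n_total` holds by
   construction, and a cell-free ROI returns a flagged undefined score, not
   0%. `find_hotspot()` slides a square ROI (1 mm² by default) at a coarse
   stride and returns the ROI maximising the index among those with at
   least `min_cells` nuclei (default 1000, the recommended minimum for a
   reliable index), ties broken by nucleus count then top-left position.

# The synthetic generators

## Slides

`generate_slide()` renders tumor nuclei as soft-edged ellipses (radius
7 ± 12% px at 0.5 µm/px, so a 1 mm² hotspot is 2000 × 2000 px), DAB-positive
nuclei with a DAB load (OD 0.70 ± 0.10) plus a light counterstain, negative
nuclei hematoxylin-only (0.55 ± 0.08), and stromal nuclei elongated
(aspect ~3) and fainter — the "background" class the classifier must reject.
The positive count is the nearest integer (ties to even) of
`positive_fraction × n_tumor_nuclei`, so scoring the generator's own ground
truth reproduces the spec fraction exactly up to that rounding. Centers are
rejection-sampled with a minimum separation of 3 radii (21 px): the 10 px
probability-map stride cannot resolve peaks much closer than two grid
cells, so denser packing would merge detections by construction rather than
by defect. Infeasible packings error with the achievable maximum. What the
generator deliberately does *not* emulate: tissue texture, staining
gradients, scanner artifacts, overlapping nuclei, pyramidal WSI formats —
so passing tests demonstrate the chain's correctness on well-posed input,
not robustness to the full messiness of scanned tissue.

## Trial tables

`generate_trial_table()` draws, per patient: pre-treatment Ki67 from a
lognormal (median 15%, log-SD 0.8) truncated to [5, 100] — hotspot indices
below ~5% are rare in ER+ disease; a post/pre ratio on the +1 scale from a
lognormal with arm-specific mean (defaults 0.65 premenopausal tamoxifen,
0.37 postmenopausal tamoxifen — i.e. ~35% and ~63% mean decreases — and
0.33 / 0.42 for anastrozole / fulvestrant, values chosen as same-magnitude
effects since only their statistical indistinguishability is reported);
log-SD 0.5; and estradiol by menopausal status (premenopausal median
300 pmol/L, postmenopausal median 15 pmol/L, so ≥90% of postmenopausal
pre-treatment values fall below the 44 pmol/L assay limit). Censored E2 is
stored at the limit with a flag, never as missing.

Two parametrisation choices deserve explanation:

* **`ratio_mean_type`.** "arithmetic" (default) makes `mean_ratio` the
  arm's expected ratio, so 0.37 yields a 63% mean decrease — the scale on
  which effect sizes are reported. "geometric" makes it the lognormal
  median; a geometric mean of 1 gives a log-ratio exactly symmetric about
  zero, which is the signed-rank test's null. The distinction is not
  pedantic: an "arithmetic mean ratio of 1" has median ratio 0.88 and a
  one-sided signed-rank size of ~0.15, an entirely real skewness effect,
  not a test defect.
* **`e2_coupling`.** The inverse E2–effect relationship is a Gaussian
  copula correlation between log post-treatment E2 and the log ratio,
  rather than a regression slope. The copula leaves the arm's ratio
  marginal untouched — arm mean decreases stay exactly at their spec values
  under any coupling strength — while inducing the rank association the
  E2-gradient analysis detects. Default 0.5; the power analyses use 0.7 as
  "strong" coupling.

## Expression matrices

`generate_expression()` emits one before and one after sample per patient:
gene baselines ~N(7, 1) on the log scale; signature genes load (uniform
0.5–1, with the set's ±1 direction) on a latent proliferation factor that
drops after treatment by `latent_scale × log10` of the patient's Ki67
ratio; genes carry 1–3 probes (60/30/10%) with probe offsets; ~2% missing
values; and an additive per-probe batch offset. The bundled gene sets
(MKI67 plus five multi-gene signatures, one with mixed direction weights)
are synthetic placeholders over the simulated gene universe — shipped as
editable two-column text files so real published lists can be dropped in.

# Statistics

* **Rank tests.** Wilcoxon signed-rank (zero differences dropped — the
  classic form, not Pratt's), Mann–Whitney and Kruskal–Wallis wrap the
  standard `stats` implementations, except that for n ≤ 12 (pairs, or
  pooled two-sample size) the null is computed by full enumeration —
  sign-flips or group assignments — which stays exact under tied
  magnitudes, where the textbook exact algorithms give up. All enumeration
  paths are verified against independent brute-force oracles in the tests.
  The paired trial tests run on log10(Ki67 + 1), the same scale as the
  (post+1)/(pre+1) log-ratio convention (zeros are defined, and the
  no-effect null is exactly symmetric there). All reported p-values are
  uncorrected and labeled with their sidedness.
* **Responders.** A responder shows a strict decrease; equality is its own
  category, coded separately from decreases and increases.
* **E2 gradient.** Among tamoxifen-treated patients with post-treatment E2
  above the detection limit (censored patients excluded), the primary
  readout is a one-sided Spearman test of negative correlation between E2
  and percent Ki67 decrease; a least-squares slope of log ratio on log E2
  is reported alongside. The underlying published statistic is unspecified,
  so neither readout claims numerical identity with it. Note one genuine
  pitfall the simulations exposed: pooling arms with different effect sizes
  and different E2 distributions confounds this gradient even with no
  within-arm coupling; the type-I simulation therefore uses equal arm
  effects.
* **Concordance.** ICC is the two-way random-effects, absolute-agreement,
  single-rater ICC(2,1) — the standard for method agreement, penalising
  systematic offsets — with the McGraw–Wong F-based CI; the consistency
  form is also exposed. The variant behind any particular published ICC is
  typically unstated, so no numerical identity is claimed. Spearman uses
  the exact permutation null for n ≤ 8.
* **Moderated t.** The paired empirical-Bayes moderated t fits its
  inverse-χ² prior by closed-form moment matching on log sample variances
  (trigamma inversion for the prior df). With `prior_df = 0` it reduces
  exactly to the ordinary paired t (tested to machine precision); with the
  fitted prior it tracks an independent reference implementation to
  correlation > 0.999 on shared fixtures, without claiming identity.
* **knn imputation.** Missing entries are filled by the mean of the k = 10
  nearest probes (Euclidean over shared observed columns, normalised by
  the shared count; ties broken by row order; donors must be observed in
  the target column). Observed values are never altered; fully missing
  rows error by name. Batch handling is either a pre-corrected input
  matrix or optional per-batch median centering, clearly labeled as a
  simple stand-in — the published empirical-Bayes batch correction is an
  external method and out of scope.

# Numerical choices and degenerate inputs

* Coordinates are 0-based, row-major, top-left; ROIs are half-open
  rectangles — stated on every interface to avoid off-by-one drift.
* Positive-count rounding: nearest integer, ties to even.
* Constant score vectors make Spearman undefined (flagged, not NaN); zero
  between-subject variance flags the ICC degenerate; all-zero paired
  differences flag the signed-rank test with p = 1.
* Detection at map borders skips the quadratic refinement on the incomplete
  axis instead of discarding border cells (discarding them measurably cost
  recall at ROI edges).
* Determinism: every generator takes an explicit seed and restores the
  caller's RNG state; fixed seeds give bit-identical images, tables,
  matrices, scores and end-to-end manifests (tested by checksum).

# Problem sizes

The shipped analyses and tests use desk-scale versions of the study
conditions, chosen once: 320 × 320 px slides (160 × 160 µm) with ~110 tumor
nuclei, a 20-ROI concordance panel spanning 5–60% positivity, 4 × 400
training windows, trial tables at the paired sample sizes 29/14/15/13, 500
replicates for effect-size recovery, 2000 for test size, 200 for power, and
a 5000-gene null for p-value uniformity. The 1 mm² / ≥1000-cell hotspot
semantics are preserved through the µm-per-pixel metadata; only the pixel
budget shrinks.

# Known limitations

* The classifier is linear on engineered features; it is calibrated to the
  synthetic stain model and will not transfer to scanned tissue without
  retraining (the contract, not the weights, is the deliverable).
* Contours are star-shaped by construction and cannot represent strongly
  concave or overlapping nuclei.
* The hotspot search is exhaustive at a coarse stride, not the exact
  argmax over all positions.
* Expression simulation ignores probe-specific dynamic range and
  intensity-dependent missingness; imputation quality claims extend only to
  missing-completely-at-random holes.
* With only 2 raters and 20 pairs the ICC confidence interval is wide;
  that is a property of the design, not the estimator.
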