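---
title: "Temporal subtraction of sequential mammograms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal subtraction of sequential mammograms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Microcalcifications — tiny calcium deposits that appear as bright specks on a
mammogram — are an early radiologic sign of breast disease. Their morphology,
spatial distribution, and *change over time* drive the BI-RADS assessment:
large, round, scattered calcifications are typically benign (BI-RADS 2),
while small, pleomorphic, tightly clustered ones that appear between two
screening rounds are suspicious (BI-RADS 4–5). Reading them is hard because
they are a few pixels wide on a textured background that itself changes
between rounds.

`tsmammo` implements a temporal-subtraction CAD pipeline for pairs of
sequential mammographic views of the same breast: the prior exam is
deformably registered onto the most recent one and subtracted, so anatomy
that has not changed — including pre-existing benign calcifications —
cancels, and *new* findings stand out against a nearly empty background.
Candidate regions segmented from the difference image are described by 96
features and classified in two rounds (normal tissue vs. true
microcalcification, then benign vs. suspicious) under patient-grouped
cross-validation.

## Pipeline stages

### Preprocessing

Both rounds of a pair are processed with identical parameters:

* `normalise()` — min–max rescaling to [0, 1]; a constant image maps to
  zeros.
* `segment_breast()` — global threshold (default 0.05) on the normalised
  image, a cleared border margin (default 4 px, removing film edges and
  markers), morphological closing, then the largest 8-connected component.
  The breast must come out as a single region; view labels and small
  artifacts are dropped by the largest-component rule.
* `gamma_correct()` — pixelwise `x^gamma` with `gamma = 2` by default.
  On the unit interval this suppresses mid-grey tissue relative to the
  brightest structures, which is where microcalcifications live. The
  exponent is exposed because the appropriate value depends on the
  detector's transfer curve.

Pixels outside the breast mask are set to zero so registration forces and
contrast statistics are confined to tissue. The mask of the *recent* view is
used for both rounds; at the deformation magnitudes we model (a few pixels)
the masked-off boundary band is negligible.

### Demons registration

`demons_register()` is the classic intensity-driven Demons scheme. With
fixed image $f$ (recent) and moving image $m$ (prior), each iteration
computes the per-pixel displacement increment

$$u = \frac{(m \circ \varphi - f)\,\nabla f}{\|\nabla f\|^2 + (m \circ \varphi - f)^2},$$

applied along the direction that decreases the squared difference under
backward (pull) warping with bilinear interpolation. The denominator bounds
every step by half a pixel, which is what makes the scheme stable. The
update is Gaussian-smoothed (fluid-like regularisation, `update_sigma = 1`
px) before being added to the field, and the accumulated field is smoothed
again every iteration (diffusion-like regularisation, `field_sigma = 1.5`
px). The procedure runs coarse-to-fine over a 3-level pyramid (×4, ×2, ×1)
with 100/60/30 iterations per level. A level stops early once the best
metric seen has not materially improved (relative tolerance `1e-5`) for
5 iterations; tracking the best field rather than the last one makes
the stop robust to transient metric increases and guarantees the final
mean squared difference never exceeds the initial one.

Two design choices matter in practice:

* **Histogram matching.** Demons assumes intensity constancy. Even after
  min–max normalisation the two rounds differ globally — the recent image's
  new findings shift its maximum, and acquisition drift shifts the prior's
  histogram — and those differences are otherwise converted into spurious
  displacement. `demons_register()` therefore quantile-matches the moving
  image onto the fixed one over the breast mask before iterating (the same
  practice as standard Demons workflows). On phantoms this single step
  roughly doubles the recovered fraction of the true deformation.
* **Field smoothing strength.** With `field_sigma = 2` px the diffusion
  regularisation plateaus at about 77% recovery of a 6-px smooth synthetic
  deformation; `1.5` px recovers 82–87% across seeds while still keeping
  the field visually smooth. We chose 1.5 px as the default and expose it
  in `demons_params()`.

When a mask is supplied, per-iteration updates outside the (blurred) mask
are damped to zero, so background noise never drives the field.

### Subtraction and elimination accounting

`subtract()` computes `diff = max(recent − warped prior, 0)` inside the
breast mask. Negative differences are clipped: new findings are brighter
than their background, and darkening carries no detection signal here. Two
summaries mirror how temporal subtraction is evaluated:

* the **contrast ratio** — maximum over mean intensity, computed over the
  breast mask (a whole-frame mean would be deflated arbitrarily by the
  empty background) — for both the recent image and the difference image;
* the **intensity reduction** — the percentage drop of mean intensity
  achieved by subtraction.

`removal_stats()` scores the elimination of unchanged ("old")
microcalcifications: an old finding counts as removed when its residual
peak in the difference image, within an 11×11 window around its centre,
falls below half its peak in the recent image (`residual_frac_threshold =
0.5`, `window_px = 5` at phantom scale; both scale with resolution). New
findings are scored with the same rule to verify none of them is removed.

### Candidate detection

`detect_candidates()` chains a local range filter (window 3: local max −
local min, replicate borders), a binarisation threshold, morphological
closing (disc radius 1) to bridge 1-px gaps, an area floor (4 px), and
8-connected labelling. Defaults are stated at phantom scale (512×416,
i.e. 1/8 of 4096×3328 full-field resolution) and scale linearly with image
size. The binarisation threshold is the pipeline's main operating
parameter; `optimise_threshold()` selects it on a labelled development set
by maximising `tp − fp` through the full detect-and-match path, breaking
ties towards the higher (more conservative) threshold.

`match_candidates()` uses greedy nearest-first one-to-one matching: a pair
is eligible when the annotated point lies inside the candidate's mask or
within 8 px of its centroid. Greedy matching is deterministic and cheap;
on configurations where annotation spacing exceeds the tolerance it
coincides with optimal assignment (asserted against brute force on small
instances), but in dense clusters it can in principle drop a match that a
global assignment would keep.

### The 96 features

Each candidate is described by exactly 96 features in a fixed, versioned
order (`feature_names()`):

* **12 shape**: area, boundary perimeter (8-connected contour length),
  eccentricity, solidity, extent, major/minor axis lengths (second central
  moments with a 1/12 pixel-extent correction), aspect ratio, equivalent
  diameter, circularity $4\pi A/P^2$, convex area (lattice-point count of
  the convex hull via Pick's theorem, so convex masks have solidity exactly
  1), orientation.
* **12 first-order intensity** over the mask pixels: mean, SD, min, max,
  median, skewness, excess kurtosis (both defined as 0 for zero-variance
  samples), mean energy, 32-bin Shannon entropy, range, 10th and 90th
  percentiles.
* **72 GLCM texture**: co-occurrence matrices at 4 angles (0°, 45°, 90°,
  135°) × 3 offsets (5, 15, 25 px) on the candidate patch (bounding box
  dilated by 2 px, quantised to 32 grey levels, *not* symmetrised),
  12 properties each — contrast, correlation, energy, homogeneity,
  dissimilarity, entropy, maximum probability, sum average, sum variance,
  sum entropy, difference variance, difference entropy — summarised as the
  mean and SD across the 4 angles, separately per offset:
  12 × 3 × 2 = 72. This mean/SD-across-angles reading is the only one
  consistent with a 72-value block on that grid. Patches smaller than
  32×32 are zero-padded so all offsets are computable; with padding in
  play the angular SDs are not exactly zero even for isotropic content,
  which is why the zero-texture invariant is asserted on unpadded patches.

The feature identities beyond the GLCM grid are this package's fixed
choice; anyone comparing to other implementations should treat them as
approximate.

`select_features()` screens every feature with Welch's two-sample t-test
(`p < 0.05`), ranks survivors by permutation importance from a
random-forest surrogate, and keeps the top 20. If nothing survives the
screen (e.g. on null data) all features enter the ranking so the selected
set is never empty.

### Classification and evaluation

Eight classifier designs are available: 9-nearest neighbours (Euclidean
distance on standardised features), a decision tree, random forest,
multi-layer perceptron (single hidden layer of 8 units, weight decay
0.01), adaptive boosting (discrete AdaBoost over depth-1 stumps, 50
rounds), bagging (25 bootstrapped trees), gradient boosting (depth 3, 50
rounds), and soft ensemble voting — the average of the other seven
classifiers' probabilities.

`train_eval()` evaluates them under a patient-grouped CV plan
(`build_cv()`: leave-one-patient-out, or grouped k-fold over patients).
Inside each fold, feature selection and standardisation use training-fold
statistics only. Pooled out-of-fold scores are thresholded at
`optimal_cutoff()` — the crossing point of the positive and negative score
distributions, i.e. the threshold minimising |FP − FN|, with ties broken
by total error and then the lower threshold — and summarised as counts,
sensitivity, specificity, accuracy, and the trapezoidal (Mann–Whitney)
AUC. `fisher_compare()` provides the two-sided Fisher exact comparison of
two pipeline variants' correct/incorrect counts.

**Balanced training folds.** Holding out one whole patient shifts the
training class prior towards the opposite class. On null data this
*systematically anti-correlates* LOPO predictions with the held-out class:
with 8 patients we measured mean accuracies of 18–42% — far below chance —
across all eight classifiers. `train_eval()` therefore equalises training
priors per fold by cyclic (deterministic) replication of minority-class
rows (`balance_train = TRUE`). With balancing, null-data accuracy is
restored to 46–53% and separable cohorts are unaffected.

`classify_two_round()` chains the two clinical questions: round 1 filters
candidates down to true microcalcifications; round 2 classifies true
microcalcifications as benign or suspicious. Round 2 defaults to the
ground-truth lesion set (so its denominators are annotation counts);
`round2_input = "round1"` instead feeds it only round-1 positives, as the
chained system would run in deployment.

## The synthetic phantom

Clinical temporal pairs with per-lesion annotations are not freely
available, so `make_phantom_pair()` generates the study conditions the
pipeline targets, with complete ground truth:

* a half-elliptical breast region against a dark background, filled with
  smooth multi-scale blob texture (Gaussian-filtered noise at scales 4–32
  px);
* "old" benign microcalcifications present in both rounds: soft-edged,
  round-ish discs of radius 2–3.5 px, contrast 0.30 above background,
  scattered with a minimum spacing of 5× the maximum radius and kept away
  from the suspicious cluster;
* "new" findings present only in the recent round: benign ones as above,
  suspicious ones at half the radius, rendered as randomly perturbed
  ellipses (angular harmonics 2–4) and packed inside a disc of radius 10×
  the mean radius — encoding the premise that morphology, distribution and
  change over time carry the diagnostic signal, without claiming clinical
  realism;
* the prior round is the recent image *minus the new findings*, warped by
  a smooth random displacement field, dimmed by a 2% global drift, with
  independent Gaussian noise (σ = 0.01) added to both rounds.

The displacement field deserves a note: the generator draws a smooth
random field `u*` (Gaussian smoothness 32 px, peak 6 px by default), and
stores `u*` as `true_field` — the field that maps the *prior into the
recent frame*, i.e. exactly what registration should recover. The prior is
built by warping with the numerical inverse of `u*` (fixed-point
iteration), so endpoint-error comparisons against `true_field` are exact
rather than approximate. The default 512×416 frame is 1/8 of full-field
resolution, which keeps a full registration run at a few seconds.

`make_feature_cohort()` complements the imaging phantom for
classifier-only studies: per-patient 96-dimensional Gaussian feature
vectors whose class means differ by a chosen separation along a random
direction, with a patient-level random offset (σ = 0.25) so grouped CV is
meaningfully different from row-wise CV.

**What the phantom does not emulate:** breast-density classes, pectoral
muscle, vessels and ductal structure, detector blur/heel effect, masses
and architectural distortions, or realistic calcification morphology
beyond size/roundness/clustering. Passing phantom tests therefore
demonstrates the pipeline's mechanics — registration recovery, exact
cancellation, change detection, leak-free evaluation — not clinical
performance.

## Numerical choices and degenerate inputs

* Constant images normalise to all-zeros rather than NaN.
* A contrast ratio over an identically zero difference image is `NA`
  (nothing remains to have contrast), and percentages over empty truth
  sets are `NA`.
* Correlation of a zero-variance GLCM is defined as 1; entropies use
  base-2 logs with `0 log 0 = 0`.
* Skewness/kurtosis of zero-variance intensity samples are defined as 0.
* Warp sampling outside the source frame returns 0.
* `optimal_cutoff()` tie-breaks are fixed (total error, then lower
  threshold) so reports are reproducible to the bit.
* All stochastic components (phantoms, cohorts, forests, boosting,
  perceptron initialisation) are seed-controlled; identical seeds give
  identical outputs.

## Problem sizes used in the validation suite

The test suite exercises registration/subtraction/detection on ten
512×416 phantoms with 6-px deformations (the package's default study
conditions), classifier behaviour on 40-patient separable cohorts and
twenty 16-patient null cohorts, and all statistical primitives against
brute-force oracles on instances of up to 50 scores. The same quantities
are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* The Demons implementation is the classic first-order scheme; it is not
  diffeomorphic, and large or sliding deformations are out of scope.
* Greedy matching can under-count matches in pathologically dense
  candidate/annotation configurations.
* The neural-network classifier design is not included; the other eight
  designs are. (A 7-layer perceptron would add a heavyweight dependency
  without changing the package's testable claims.)
* Feature identities outside the GLCM grid are the package's own fixed
  set, not a community standard.
* DICOM support is intentionally minimal: single-frame monochrome,
  explicit VR little endian, uncompressed.
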