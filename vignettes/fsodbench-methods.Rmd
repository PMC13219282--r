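---
title: "Methods: few-shot split optimization, matching metrics, and the crop-classification cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: few-shot split optimization, matching metrics, and the crop-classification cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsodbench)
```

`fsodbench` provides the three quantitative components of a few-shot object
detection (FSOD) benchmark for microscopy: the construction of
test/support splits by certified-exact integer optimization, detection
scoring by one-to-one optimal matching over an IoU threshold sweep, and the
crop-and-classify cascade harness. This vignette documents the models,
their assumptions, the tunable parameters, and the numerical and design
choices, in the package's own terms.

## Data model

A dataset is an `od_pool`: a table of images (id, source tag, pixel
dimensions) and a table of ground-truth boxes in continuous corner
coordinates `(x_min, y_min, x_max, y_max)`, x rightward, y downward, with
`area = (x_max − x_min)(y_max − y_min)` and no ±1 pixel adjustment. This
convention makes every IoU formula exact and matches how segmentation
models report candidate rectangles. Boxes may touch image borders; boxes
*crossing* a border are rejected at construction rather than clipped, so
annotation errors surface at read time. COCO-style JSON is the only
interchange dialect in v1 (both common public microscopy corpora ship it);
`bbox = [x, y, w, h]` is converted on read via `x_max = x + w`.

## Split optimization

### The two phases

For each source independently, exactly `n_support` images are chosen out of
the source pool (defaults 10 of 63, leaving `n_test = 53`). Phase 1
maximizes the *class–image coverage*

$$\mathrm{Cov} = \sum_c \sum_i a_{ci} x_i, \qquad
a_{ci} = \mathbb{1}[\text{image } i \text{ contains class } c],$$

i.e. the count of (class, support-image) presence pairs. We adopt the
presence-pair count rather than the number of distinct classes covered at
least once: with 10 support slots the distinct-class reading saturates
immediately and leaves the objective without slack, whereas the pair count
is exactly the numerator that drives class-presence coverage (CPC) below.

Phase 2 locks coverage at the recorded optimum `Cov*` and maximizes the
scalarized objective

$$\sum_c w_c r_c \;-\; \lambda \sum_c s_c,$$

with `s_c` the support box count of class `c`, `r_c = n_c − s_c` the
reference-side boxes, and `w_c = 1/n_c` the per-source inverse-frequency
weight. The weighted first term keeps the reference side rich in rare
classes; the second term discourages surplus support boxes. The two aims
are combined by a weighted sum (one certified solve, matching their
simultaneous formulation) rather than lexicographically;
`lambda_surplus = 1` by default and configurable. An optional per-class
floor `min_support_boxes_per_class` (default 0, i.e. off) can force a
minimum number of support boxes per class.

### Exact solving without an external MIP library

Both phases have objectives that are linear in the per-image selectors with
per-image coefficients, so certified optimality does not require a generic
branch-and-bound backend:

- Phase 1 reduces to picking the `n_support` images with the most distinct
  classes (the coverage contribution of an image is independent of the
  rest) — exact by construction.
- Phase 2 is "select exactly `n` items with `Σ d_i x_i = Cov*` minimizing a
  linear cost", solved by dynamic programming over (selected count,
  coverage) in `O(N · n_support · Cov*)` — exact, and fast enough for
  thousands of trials.
- With a per-class floor active, the DP state would need per-class counts,
  so that variant is solved by exhaustive depth-first search with
  admissible pruning (cost lower bound from the sorted remaining costs,
  coverage reachability bounds, per-class remaining-box bounds) — still
  exact, intended for the small pools where the floor matters.

All three routes are validated against `brute_force_split()`, an
independent subset-enumeration oracle, in the test suite.

### Trials, tie-breaking, and the Support-Spread Score

Branch-and-bound MIP solvers return *one* optimal vertex, and which one
depends on variable ordering. We reproduce that degree of freedom
explicitly: the solve is repeated over `trials` (default `T = 1000`)
shuffled image orderings, trial `t` (0-based) shuffling with seed
`base_seed + t`; within a solve, ties in the exact optimizers are broken
toward images earlier in the shuffled ordering. The optimum value is
ordering-invariant — only the selected set varies across trials. Each
trial's pooled support set (union over sources) is scored by

$$\mathrm{SSS} = \mathrm{CPC} \times \mathrm{CBE},$$

where CPC is the mean over all classes of the fraction of support images
containing the class (presence, not multiplicity — an image with nine boxes
of a class counts once), and CBE is the Shannon entropy of the support box
distribution over classes normalized by `log |C|`. The maximum-SSS trial
wins; ties retain the earliest trial. Trials whose solve fails are
discarded and counted (with the built-in exact solvers this does not occur,
but the accounting mirrors a backend whose certificate can fail).

Three conventions matter and are deliberate:

- `|C|` in the CBE normalization is the *pool's* class universe, not only
  the classes present in the support set: a support split that misses a
  class entirely should score as unbalanced, not get a smaller denominator.
- `|C| = 1` makes CBE equal 1 (a one-class distribution is trivially
  balanced).
- SSS is computed on the support set pooled across sources rather than
  averaged per source; per-source constraints are already enforced by the
  per-source solves, and the pooled score reflects what a K-shot sampler
  will actually draw from.

## Matching metrics

Detections are matched to ground truth *once per image* by the Hungarian
algorithm maximizing total IoU (delegated to `clue::solve_LSAP()`), and
only then thresholded — matching first and counting second keeps F1
monotone along the threshold grid, which the evaluator asserts on every
run. Pairs with IoU exactly 0 are dropped even below the lowest threshold:
a non-overlapping pair is not a detection of the object. Matching is
class-aware by default (misclassified localizations count as one FP plus
one FN), with a class-agnostic flag for localization-only studies.

Counts are pooled over images (micro-averaging), and precision, recall and
F1 are computed at 50 evenly spaced thresholds from 0.05 to 0.70 inclusive
(step 0.65/49; the count and endpoints are fixed, even spacing is our
choice). `mF1` is the mean of the 50 F1 values. `Mean IoU (TP@0.5)` is the
mean IoU of pooled matched pairs at or above 0.5, defined as 0 when no such
pair exists; because it conditions on success it complements mF1 by
separating loose localization from missed coverage. All zero-denominator
precision/recall/F1 cases are defined as 0. When scores from multiple
datasets are combined, the CLI reports the unweighted mean of per-dataset
mF1 alongside pooled counts, and both class-awareness and aggregation are
explicit flags rather than silent defaults.

Non-maximum suppression follows the standard greedy rule: drop detections
scoring below `score_threshold` (default 0.05), process the rest in
descending score order (stable for ties), and suppress a detection whose
IoU with an already-kept detection of the same class exceeds
`iou_threshold` (default 0.50). The defaults are the operating point common
for open-vocabulary detector output.

## The cascade

The cascade reproduces the decoupled localization/classification pipeline:
class-agnostic proposals (from an external segmentation model, consumed as
a COCO results file — no model inference happens in this package) are
padded by `pad = 10` px, clipped to the image, cropped, and resized to
`out_size = 128` px squares by bilinear interpolation before
classification. Resampling uses the half-pixel-center convention with edge
clamping, so a grid-aligned box of the output size reproduces its source
pixels exactly; the 2×2→4×4 closed form is frozen in the tests and agrees
with reference bilinear resamplers. The emitted detection reuses the
*unpadded* proposal box: padding is classifier context, not a localization
refinement.

Support sets hold exactly `k` crops per class (`k` counts shots *per
class*, consistent with per-class support minima in published split
tables; a total-count interpretation can be emulated by constructing
`support_set()` directly). `sample_support()` draws them uniformly without
replacement under an explicit seed, mirroring protocols that fix shot
sampling seeds (e.g. 42/123/456) across trials.

The classifier is a contract, `(crop, support) → (label, confidence)`, so
external models plug in at exactly one point. The shipped
`baseline_classifier()` is a deterministic nearest-centroid rule over a
fixed feature map (8×8 mean-pooled grayscale intensities plus global mean
and standard deviation, softmax of negative distances for confidence,
lexicographic tie-break). It is a test vehicle: strong on
morphology-separable synthetic classes (its agreement on the frozen
separable fixture at `k = 6` was 1.0 when recorded), and not a substitute
for a learned classifier on real imagery.

## The synthetic generator

`generate_dataset()` emulates the aspects of multi-source microscopy pools
that the machinery above is sensitive to: several sources, dense fields of
small elliptical cells with class-dependent size/elongation/intensity,
imbalanced class abundances (configurable per-class weights; the default
palette includes a 5% rare class so rare-class behaviour of the optimizer
and of CBE is exercised), overlap allowed, anti-aliased rendering over
Gaussian background noise. Defaults follow the benchmark's study
conditions where they exist — four sources of 63 images each, supporting
the 53/10 per-source split — and otherwise values a microscopist would
call plausible: 384 px frames (between common camera crops), 8–30 cells
per image, cell radii of 6–14 px, background 0.15 with noise sd 0.03.

All randomness flows from one explicit seed; annotations and pixel noise
use separate derived streams, so the pool is bit-identical whether or not
rasters are rendered. `perturb_detections()` corrupts ground truth into
synthetic detections with independent knobs (coordinate jitter, box drops,
spurious boxes per image, label flips), each of which degrades mF1
monotonically in expectation — the property the acceptance tests check
over 30 seeds.

What passing these tests shows is that the *machinery* is correct:
splits are certified-optimal and reproducible, metrics match closed-form
and brute-force oracles, the cascade preserves boxes and classifies
separable morphologies. What it does not show is performance on real
microscopy: the generator has no staining variation, phase-contrast halos,
debris, uneven illumination, or inter-class morphological ambiguity, so
classifier accuracies measured here are upper bounds of convenience, not
predictions.

## Numerical choices and degenerate inputs

- Phase-2 DP backtracking treats costs within `1e-9` as tied (floating
  sums of inverse-frequency weights); the brute-force comparisons in the
  tests use the same tolerance.
- SSS comparisons across trials use a `1e-12` strict-improvement margin,
  so floating noise cannot steal a tie from the earliest trial.
- `normalized_entropy()` uses the natural log and the `0·log 0 = 0`
  convention; base invariance is property-tested.
- Empty support sets, support sets without boxes, and detections for
  unknown images are errors, not silent zeros; a pool-universe class
  absent from the support contributes 0 to CPC and depresses CBE.
- Jittered boxes are clipped to the image and re-inflated to a minimum
  1 px side if inverted, keeping every synthetic detection valid.
- Images are numeric arrays on `[0, 1]`; integer-coded PNG/TIFF input is
  rescaled by the readers on load.

## Problem sizes in the shipped tests

The test suite and acceptance script are sized for interactive runs on one
CPU: oracle-equivalence suites use 30 random two-source pools of 5–8
images and 100 matching instances up to 6×6 (exhaustive enumeration on
both sides); the corruption-monotonicity study uses 6-image pools over 30
seeds; the full-protocol split optimization in the acceptance script runs
the complete 4 × 63-image, 1000-trial configuration, which completes in
seconds thanks to the DP solver.

## Known limitations

- Only COCO-dialect JSON is supported; YOLO-txt and Pascal-VOC XML are out
  of scope for v1.
- The ILP solver is specialized to the structure of these two phases; it
  is not a general MIP interface (by design — certified optimality is the
  contract, and the structure admits exact polynomial routes).
- The per-class floor variant falls back to exhaustive search and is meant
  for small pools.
- Crowd/ignore regions, mask-level metrics, and confidence-sweep PR curves
  are not implemented; the evaluator scores boxes only.
- The baseline classifier is intentionally simple; real few-shot
  classification quality must come from the pluggable classifier.
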