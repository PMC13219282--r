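# fsodbench

Benchmarking machinery for **few-shot object detection (FSOD) in optical
microscopy**. Modern detectors and vision-language models can be adapted to
new cell types from a handful of annotated examples, but measuring that
ability fairly requires three pieces of infrastructure that are usually
improvised per paper:

1. **Principled few-shot splits.** Given per-source pools of bounding-box
   annotated microscopy images, the pool must be partitioned into a small
   *support* (example) split and a disjoint *test* (reference) split so that
   the support images jointly cover all cell classes and carry a balanced
   box distribution — otherwise rare classes (a handful of schizonts among
   thousands of red blood cells) are unlearnable from the shots provided.
2. **Consistent detection scoring.** Densely packed cells make greedy
   box matching exploitable by duplicate predictions; one-to-one optimal
   matching and a threshold sweep are needed for a stable score.
3. **A reproducible cascade harness.** The strongest few-shot pipelines
   decouple localization (class-agnostic proposals from a segmentation
   model) from classification (a few-shot classifier applied to padded,
   resized crops); the plumbing around the classifier should be fixed and
   testable while the classifier itself stays pluggable.

`fsodbench` implements all three as a tidyverse-native R package, plus a
seeded synthetic microscopy generator so that every stage is testable
without downloading data. It interoperates with COCO-style JSON for
annotations and detection results, so splits and scores can be exchanged
with Python detector stacks; it is compatible with multi-source few-shot
cell detection corpora published in that format, such as the Micro-OD
collection.

## The methods in brief

**Split optimization.** For each source, exactly `n_support` of the pool's
images are selected by a two-phase integer programme, solved to certified
optimality. With binary selectors `x_i` and presence indicators
`a_ci = 1` iff image `i` contains class `c`:

- *Phase 1* maximizes class–image coverage
  `Cov = Σ_c Σ_i a_ci x_i` subject to `Σ_i x_i = n_support`,
  recording the optimum `Cov*`.
- *Phase 2* locks `Σ_c Σ_i a_ci x_i = Cov*` and maximizes
  `Σ_c w_c r_c − λ Σ_c s_c`, where `s_c` and `r_c` are the support and
  reference box counts of class `c` and `w_c = 1/n_c` is the
  inverse-frequency weight, so that abundant classes cannot dominate.

The two-phase solve is repeated over `T` shuffled image orderings (the
optimum is ordering-invariant; tie *selection* is not), and the candidate
split maximizing the **Support-Spread Score** is retained:

```
SSS = CPC × CBE
CPC = mean_c ( #support images containing c / n_support )
CBE = H(p) / log |C|,   p_c = s_c / Σ_c s_c
```

**Evaluation.** Predictions are matched to ground truth once per image by
maximal-total-IoU Hungarian assignment; pooled TP/FP/FN counts then yield
precision, recall and F1 at each of 50 IoU thresholds evenly spaced on
[0.05, 0.70]. The headline score is their mean, **mF1**, complemented by
the **Mean IoU of true positives at IoU 0.5**. Non-maximum suppression and
score thresholding are provided for raw detector output.

**Cascade.** Each class-agnostic proposal box is padded by 10 px, clipped,
cropped, resized to 128 × 128 by bilinear interpolation and passed with a
K-shot support set to a pluggable classifier `(crop, support) → (label,
confidence)`. A deterministic nearest-centroid baseline classifier ships
with the package.

## Worked example

```r
library(fsodbench)

cfg <- fixture_config(n_images = 13,
                      sources = c("brightfield", "phasecontrast"),
                      image_size = 256, cells_per_image = c(6, 14),
                      seed = 42)
ds <- generate_dataset(cfg, render = FALSE)
ds$pool
#> <od_pool> 26 images, 257 boxes, 5 classes
#>   sources: brightfield (13), phasecontrast (13)
#>   classes: round_small, round_large, spindle, polygonal, ring

split <- optimize_split(ds$pool, split_config(n_support = 3, n_test = 10,
                                              trials = 100, base_seed = 42))
split
#> <od_split> 6 support / 20 test images over 2 source(s)
#>   SSS = 0.8893 (CPC = 0.9333, CBE = 0.9528), winning trial 0 of 100
```

The three support images per source cover 93% of (class, image) presence
opportunities (CPC) and hold a nearly balanced box distribution
(CBE = 0.95); their product, SSS = 0.89, is the criterion that selected
this split among all certified-optimal candidates.

```r
det <- perturb_detections(ds$pool, jitter_sd = 2, drop_rate = 0.1,
                          fp_rate = 0.5, seed = 7)
ev <- evaluate_detections(det, ds$pool)
ev
#> <od_eval> 249 detections vs 257 ground truths (class-aware)
#>   mF1 [0.05:0.70] = 0.7966   Mean IoU (TP@0.5) = 0.6812
#>   at IoU 0.5: TP 199, FP 50, FN 58
autoplot(ev)   # precision/recall/F1 across the 50-point threshold sweep
```

Mildly corrupted detections (2 px box jitter, 10% dropped boxes, spurious
boxes at rate 0.5/image) cost about 0.20 of mF1 and pull the mean matched
IoU down to 0.68 — the two metrics separating coverage errors from loose
localization.

Results follow broom conventions (`tidy()`, `glance()`), and a thin CLI
(`inst/scripts/fsodbench`) exposes `split`, `score-split`, `evaluate`,
`crop`, `cascade` and `simulate` over files.

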