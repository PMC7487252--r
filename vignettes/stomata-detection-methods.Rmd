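---
title: "Patch-based stomata detection: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based stomata detection: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Stomatal density — stomata per square millimeter of leaf surface — is a
core plant functional trait, and counting stomata on light-microscope
images of epidermal impressions is slow when done by eye. `stomatadetect`
implements an automated leaf-to-coordinates workflow that treats detection
as *patch classification*: a micrograph is divided into overlapping
120 × 120 px windows by a sliding-window scan, a small convolutional
network scores each window for the presence of a *fully visible* stoma,
windows at or above a confidence threshold are clustered with flat-kernel
mean-shift, and each cluster mode becomes one stoma coordinate. Counts are
then converted to densities through the microscope calibration (the
reference optics map 1,600 × 1,200 px onto a 344 × 258 µm field, i.e.
0.215 µm/px and an unrounded 0.088752 mm² view field).

This is deliberately the simplest credible detector — no region proposals,
no bounding-box regression — which makes every stage separately testable:
the labeling rule is a geometric predicate, the clustering has an exactly
checkable fixed point, and the evaluation is standard information
retrieval (precision, recall, F, threshold sweeps, count accuracy, a
computed-versus-manual counts regression).

## The patch classifier

Three reference architectures are specified declaratively and counted
exactly by integer arithmetic (`count_parameters()`), independent of any
numerical backend:

| name | convolutions | dense head | parameters (trainable) |
|---|---|---|---|
| `basic_shallow` | 8–16–32, 3×3 valid, each + 2×2 max pool | 32, 32, softmax 2 | 180,242 |
| `basic_deep` | 32–64–128, same topology | 1,024, 1,024, softmax 2 | 23,297,090 |
| `vgg19` | standard 16-conv VGG19 base (frozen) | 4,096, 2,048, softmax 2 | 47,297,602 (27,273,218) |

The shape conventions — valid padding for the basic nets, 'same' for the
VGG19 base, 2×2 floor-halving pools — are pinned down by the parameter
totals themselves: on a 120 × 120 × 3 input the basic chain shrinks
120 → 118 → 59 → 57 → 28 → 26 → 13, giving a 13·13·32 = 5,408-feature
flatten for `basic_shallow`, and the VGG19 base ends at 3 × 3 × 512 =
4,608 features. These are the only conventions that reproduce the counts
above, and the test suite asserts all five printed totals to integer
equality.

Training uses Adam (β₁ = 0.9, β₂ = 0.999) with per-architecture defaults
of learning rate 5e-4 / 5e-5 / 5e-6, batch 32 / 64 / 128 and 200 / 200 /
50 epochs; every run in this package's tests overrides the epoch count
downwards, which is stated with each experiment. Because no deep-learning
framework is available as an R dependency, the package ships its own
numerical engine (`src/cnn.cpp`): im2col + BLAS GEMM convolutions in
single precision, exact max-pool argmax routing, inverted dropout, and a
hand-rolled mt19937-based RNG so that initialization, shuffling, dropout
masks and augmentation draws are reproducible bit-for-bit across
platforms. Backpropagation is verified against finite differences in the
test suite. Pretrained VGG19 weights are not shipped; building `vgg19`
random-initializes the frozen base and warns, which preserves the
parameter bookkeeping but not ImageNet features.

Design choices where the method description is open:

* **Input normalization** — pixels in [0, 1] (8-bit / 255); grayscale
  images are replicated to the three input channels.
* **Dropout** — applied on the dense layers; the rate is exposed
  (`training_hyperparams(dropout_rate=)`) with default 0.5. For the
  desk-scale regime used in the shipped experiments (tens of epochs
  rather than 200) we train with 0.1: at 0.5 the 32-unit head of
  `basic_shallow` is regularized so hard that softmax confidences stay
  compressed far below the 0.7 operating threshold long after the
  ranking of positives over negatives is learned (at 30 epochs the
  confidence ceiling is ≈ 0.25 at rate 0.5, ≈ 0.6 at 0.25 and ≈ 0.9 at
  0.1, while the ranking quality is similar). This is a
  calibration-speed effect of few-epoch training, not a capacity effect.
* **Augmentation** — rotations restricted to 90° multiples plus
  independent horizontal/vertical flips: these are exact pixel
  permutations, so they preserve intensity histograms and, because a
  fully contained stoma stays fully contained under them, labels.

## The labeling rule and its geometry

A window is labeled *positive* iff the axis-aligned square of side
`length_px` centered on an annotated stoma lies entirely inside it
(partially visible stomata are negative). Annotations carry no
orientation, so the square is a deliberate, testable proxy for "the whole
stoma is visible".

This rule has a sampling consequence that the package documents rather
than hides: with patch size *P* and stride *s*, the window origins that
fully contain a stoma of extent *L* form an interval of length *P − L*
per axis, which is guaranteed to contain a grid origin only when
*L ≤ P − s*. At the default *P* = 120, *s* = 30, stomata larger than
90 px can straddle every window boundary, and then even a perfect
containment classifier produces no positive window. The generator's
default size range keeps the full 60–120 px span that the detector is
specified for, while the geometric validation experiments (oracle
recovery, end-to-end learning) use the detectable 60–90 px subrange where
exact recovery is provable. Users targeting large stomata should reduce
the stride or increase the patch size.

Training sets keep every positive window and subsample negatives to a
6 : 1 ratio (the imbalance of a 12,000-positive / 72,000-negative
reference corpus), seeded for reproducibility.

## Mean-shift clustering and coordinates

Thresholded window centers are clustered with *flat-kernel* mean-shift:
every point iterates to the mean of all original points within the
bandwidth until the largest displacement is below 10⁻³ px (cap 300
iterations); converged positions closer than half the bandwidth merge by
single linkage; each mode's coordinate is the mean of its members'
converged positions, its confidence the maximum member score, its size
the member count. The flat kernel was chosen over a Gaussian because its
fixed points are exactly checkable — the test suite compares the
implementation against an independent per-point brute-force oracle to
0.1 px on hundreds of random instances. The bandwidth default of 60 px
(half a patch, roughly a stoma radius) is a package choice and is
config-exposed, as is the minimum cluster size (default 1).

With the default geometry the cluster mode lands within ~21 px of the
true center: the generator places stomata with a border clearance of
`major/2 + 30` px, which guarantees at least two containing windows per
axis at stride 30, bounding the mean window-center offset by 15 px per
axis. A bare `major/2` margin would admit stomata whose single containing
window sits 30√2 ≈ 42 px off-center.

## Evaluation conventions

* **Matching** is greedy one-to-one by ascending distance within a 60 px
  radius (half a patch). The matching rule is a package construction —
  detection papers often leave it implicit — and greedy was preferred
  over optimal assignment for transparency; an exhaustive
  maximum-cardinality oracle in the tests confirms greedy is optimal on
  the small instances where enumeration is feasible. A multiply-detected
  stoma counts one TP plus extra FPs.
* **Averaging** across images is *micro* (pooled TP/FP/FN) throughout;
  per-image macro averages can be computed from the per-scene match
  results if needed.
* **Count accuracy** is the deviation form
  `100·(1 − |computed − manual|/manual)`, floored at 0 — the only reading
  under which a 36 % count deviation is 64 % accuracy. It is symmetric in
  over- and under-counting and undefined (skipped with a warning) for a
  zero manual count.
* **The counts regression** is ordinary least squares of computed on
  manual counts via `stats::lm`; the slope t-test p-value is reported but
  is not a headline quantity.

The threshold sweep uses the 19-point grid 0.05–0.95 in steps of 0.05,
with F iso-line values 0.1–0.9 attached for plotting; the operating
default is τ = 0.7, the precision/recall trade-off point the workflow is
calibrated around.

## The synthetic-data generator

Real leaf-impression micrographs are not distributable inside a package,
so every experiment runs on seeded synthetic scenes that emulate the
imaging conditions: a light mottled epidermis background (two octaves of
bilinear value noise), elliptical stomata at uniform random orientation
with a dark pore slit along the major axis, a lighter guard-cell rim and
a faint outline, plus negative-class artifacts — dark curved hair
streaks, bright-cored dark-rimmed bubbles, soft smudges — additive pixel
noise, Gaussian blur (via `EBImage::gblur`), and 8-bit quantization.
Artifact placement rejects positions overlapping stomata so synthetic
labels stay unambiguous. Determinism is byte-exact: all drawing flows
from one seed through R's Mersenne-Twister with fixed generator kinds,
and dataset files (PNG + CSV) are identical across runs and platforms.

Defaults describe the study conditions: 1,600 × 1,200 px scenes, major
axes uniform in 60–120 px, aspect ratio 0.4–0.8, minimum center
separation 140 px (so a 120 px patch contains at most one full stoma,
keeping the labeling rule unambiguous), 15–35 stomata per scene
(≈ 170–400 mm⁻² at the reference optics, a realistic range for tropical
trees), ≈ 3 artifacts per scene, noise σ = 0.02, blur σ = 1 px. The
default contrasts give a clean, high-contrast "easy" regime; harder
regimes (lower contrast, more noise, more artifacts) are one config away.

What the generator does *not* model: species-specific stomatal
morphology (kidney- versus dumbbell-shaped guard cells), epidermal cell
tracery, uneven illumination, focus-stacking artifacts, and hairy or
velvety surfaces that defeat the impression method itself. Passing tests
on synthetic scenes therefore demonstrate that the pipeline machinery is
correct and that the classifier can learn this family of appearances —
not that any fixed set of weights transfers to real micrographs, which
is always a data question.

## Problem sizes used in the shipped experiments

The packaged tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes on one CPU core while still
exercising the real 120 × 120 architecture end to end: unit fixtures use
420 × 340 px scenes and a 30-epoch training run on ≈ 250 patches; the
end-to-end learning experiment trains `basic_shallow` for 30 epochs on
≈ 2,000 patches from six full-size scenes and evaluates on six held-out
scenes, as does the acceptance script (with three held-out scenes). The
`basic_deep` and `vgg19` architectures are built and counted but not
trained in the tests (a 23 M- or 47 M-parameter training run is not a
test-suite-sized computation); the training code path is identical for
all three.

## Known limitations

* Stomata larger than `patch − stride` px are structurally missable (see
  the geometry note above); the paper-scale 60–120 px range implies a
  stride ≤ 30 recovers only sizes up to 90 px exactly.
* The per-point flat-kernel mean-shift is O(n²) per iteration — ample
  for the hundreds of positive windows per micrograph it is applied to,
  but not intended as a general clustering library.
* Greedy matching can in principle fall below the optimal assignment's
  TP count on adversarial geometry; with 140 px separations and a 60 px
  radius this does not occur.
* The CNN engine supports exactly the layer vocabulary the architectures
  need (3×3 conv, 2×2 pool, dense, dropout, softmax); it is a faithful
  training backend, not a framework.
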