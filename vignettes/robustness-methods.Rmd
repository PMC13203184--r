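---
title: "Benchmarking echocardiographic view classifiers under simulated artifacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking echocardiographic view classifiers under simulated artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Automatic classification of apical transthoracic echocardiography (TTE)
views — two-chamber (A2C), three-chamber (A3C), four-chamber (A4C) and
five-chamber (A5C) — is a routine front end of quantitative cardiac
pipelines. Models are usually evaluated on reference-quality frames, yet
clinical images carry artifacts: streaking from probe or patient motion,
signal-free cones behind ribs or prostheses, and the granular speckle
interference inherent to ultrasound. `echorobust` implements a structured
robustness analysis for this setting: parametric artifact simulators with
calibrated severity grids, frame- and sequence-level metrics, and
sequence-clustered bootstrap inference, composed into
"artifact type × severity → degradation curve" experiments.

Because clinical echo datasets are rarely shareable, the package also ships
a synthetic phantom generator that reproduces the *statistical shape* of a
typical study dataset, so the full pipeline is testable end to end without
protected data.

## The phantom generator

`generate_dataset()` draws short clips of sector-shaped B-mode-like frames.
Each frame is a fan (apex at the top centre, half-opening 40°, depth 95% of
the image height) of bright tissue at mean level 0.55, textured by a
multiplicative log-uniform speckle field (log-multiplier uniform on
±√3·σ with σ = 0.15, i.e. unit mean and standard deviation ≈ σ),
containing 2–5 dark elliptical "chambers" at level 0.10. Chamber
boundaries are not razor-sharp: the darkness blends into tissue over the
outer 40% of each chamber's normalized radius
(`chamber_edge_softness = 0.4`), mirroring the diffuse blood–tissue
interfaces of real B-mode imaging. This matters for degradability — with
hard binary edges the chambers stay statistically detectable under even
extreme multiplicative noise (clipping maps different intensity levels to
different white-pixel densities along a sharp contour), whereas soft
edges let severe speckle obscure the boundaries, as severe speckle does
in clinical images. Chamber count and arrangement encode the view class;
layouts are perturbed per clip (centre jitter ±1% of image size, axis
scaling ×U(0.9, 1.1)) and rejected/resampled if a chamber would leave the
sector or touch a neighbour. Within a clip all
frames share one layout; frame *k* of *n* is rendered at cardiac phase
*k/n* with sinusoidal ±10% modulation of the chamber axes and a rigid
jitter of at most 2 px, so frames of one clip are more similar to each
other than to frames of other clips — the intra-clip correlation that
motivates clustered inference downstream.

The default configuration reproduces the study conditions the package
emulates: 217 clips and 2170 frames of 256×256 pixels with class totals
A2C 518, A3C 390, A4C 1075, A5C 187 (about 10 frames per clip). Because
1075 frames cannot be split over 107 clips of exactly ten frames, each
class's total is spread by largest remainder, giving clips of 9–11 frames —
consistent with clips of "several to a dozen" frames averaging ten. A fixed
master seed makes generation byte-for-byte reproducible, including the
8-bit grayscale PNG export.

What the phantoms deliberately do **not** model: point-spread-function
blur, scanline geometry, spatially correlated clinical speckle, anatomical
variability beyond ellipse perturbations, pathology. Passing tests on
phantoms therefore demonstrates the *pipeline's* correctness and the
qualitative degradation behaviour of image classifiers, not clinical-grade
accuracy; the phantom classes are constructed to be separable, so absolute
baseline metrics saturate near 1 and are not comparable to clinical values.

## Artifact simulators

All three families are exact identities at severity 0 and clip outputs to
[0, 1].

**Motion blur** convolves each row with a normalized horizontal box kernel
of length *L* (pixels), the classic uniform linear-blur kernel. The
severity grid 0–20 in steps of 2.5 contains fractional lengths, so the
kernel is defined as a continuous box of width *L* sampled on the integer
grid: the tap at offset *i* receives overlap([i−½, i+½], [−L/2, L/2])/L.
This keeps every grid value exactly normalized and symmetric (e.g. L = 4 →
(0.125, 0.25, 0.25, 0.25, 0.125); L = 2.5 → (0.3, 0.4, 0.3)); L ≤ 1 is the
identity. Borders are handled by reflection so that edge intensity is not
darkened; a constant image is preserved exactly.

**Acoustic shadowing** superimposes a cone with vertex at the top centre
(the probe position) widening to a base of width *wf*·W on the bottom row:
pixel (x, y) is shadowed iff |x − W/2| ≤ (wf·W/2)·(y/(H−1)). The opening
angle is derived from *wf*, never an independent input. Shadowed pixels are
*replaced* by |ε| with ε ~ N(0, (0.03·mean(I))²) — "a few percent of the
mean image brightness" fixed at 3% — giving a heterogeneous, weakly noisy
shadow rather than pure black. The magnitude is taken so the fill stays
non-negative. Grid: wf = 0 … 0.7 in steps of 0.1; at 0.7 the widest row
spans 70% of the image width (±1 px of discretization).

**Speckle** is multiplicative Gaussian noise, I·(1 + z) with
z ~ N(0, σ²) i.i.d. per pixel, clipped to [0, 1]; noise scales with local
brightness, as real speckle interference does. σ ("noise amount") is the
dimensionless standard deviation of the multiplicative term and is *not*
rescaled by mean image brightness; the grid σ = 0 … 3 in steps of 0.5
follows the result tables of the degradation protocol, whose upper end
destroys essentially all anatomical contrast.

`apply_artifact()` seeds each stochastic corruption from
(experiment seed, frame id, family, severity) via a 31-bit string hash, so
runs are reproducible and frames mutually independent regardless of
evaluation order.

## Dataset handling

The train/test split is drawn at *sequence* level (all frames of a clip on
one side), stratified by class: the global 20% test quota is allocated
across classes by largest remainder, each class keeping at least one test
and one training sequence, so 217 sequences yield exactly 43 test
sequences. The validation split (20% of training frames) is stratified at
*frame* level, deliberately reproducing the common protocol in which
frames of one clip can reach both sides; this leaks intra-clip correlation
into validation and is flagged as such — `by_sequence = TRUE` provides the
leakage-free variant, off by default for fidelity. Training-time
augmentation is random rotation (±10°, bilinear, zero fill) and horizontal
flips with probability ½, applied only to training-fit frames.
`preprocess_frame()` implements the standard pretrained-backbone
convention — bilinear resize to 256×256, replication of the grayscale plane
to three channels and per-channel standardization with the published
ImageNet statistics, recorded as configuration data. Interpolation is
bilinear throughout (the convention is not otherwise pinned down).

## Classifiers

Classifiers are pluggable behind `predict_proba()`, which always returns a
prediction table: frame id, sequence id, true label, one calibrated
probability column per class, and the argmax prediction (ties to the lowest
class index).

*HOG + SVM*: grayscale resize to 128×128, histogram-of-oriented-gradients
descriptor (9 unsigned orientation bins, 16-px cells, 2×2-cell blocks with
L2-hys normalization) and an RBF-kernel SVM with Platt-calibrated
probabilities. The descriptor and SVM hyperparameters are documented
configuration defaults, not claims of fidelity to any particular reference
implementation.

*Small CNN*: a from-scratch convolutional network (three 3×3 blocks with
ReLU, 2×2 max-pooling after the first two, global average pooling, dropout
0.3, linear head) trained with AdamW (decoupled weight decay 10⁻⁴, separate
backbone/head learning rates), class-weighted label-smoothed (0.05)
cross-entropy, inverse-frequency weighted sampling (weights N/(K·n_k)),
cosine learning-rate annealing and early stopping (patience 5) on
validation loss, retaining the best-validation weights. It is implemented
with vectorized im2col matrix products in base R, needing no GPU or
external framework. The configuration defaults mirror the fine-tuning
recipe of pretrained backbones (learning rates 10⁻⁴/5·10⁻⁴); a
from-scratch network at desk scale learns faster with larger steps, so the
test suite and examples use input 48×48, channels 12/24/48 and learning
rates 2·10⁻³/8·10⁻³, which reaches sequence-level balanced accuracy 1.0 on
the default phantom test split in about thirty epochs.

*Frozen extractor + logistic regression*: any fixed frame-to-vector
extractor combined with ridge-penalized multinomial logistic regression
(`glmnet`), the penalty chosen by validation log-loss and recorded in the
model object.

## Metrics

All quantities are computed from prediction tables. Balanced accuracy is
the unweighted mean of per-class recalls; classes absent from a (possibly
resampled) table are dropped rather than counted as recall 0, which keeps
bootstrap replicates well-defined when a rare class's sequences are not
drawn. Per-class AUC uses the one-vs-rest rank-sum statistic with midrank
tie handling (identical to the trapezoidal ROC area); macro-AUC is the
unweighted class mean, computed over defined classes with a warning
otherwise. F1 is 2PR/(P+R), defined as 0 at P = R = 0. Sequence-level
results average frame probability vectors within each clip and take the
class of the highest mean. Formatted output rounds half-up at three
decimals; full precision is always retained internally (0.8665 prints as
0.867 in text and 0.866 under round-half-even, which is why both appear in
published summaries of the same quantity).

## Clustered bootstrap inference

Frames of one clip are statistically dependent, so uncertainty is
quantified by resampling *sequences* with replacement — as many as
observed, keeping all their frames — and recomputing the metric on the
concatenated replicate; 95% confidence intervals are the 2.5th/97.5th
empirical percentiles (interpolated order statistics, `quantile` type 7)
over B = 1000 replicates. Effects of degradation are measured as
Δ = metric(degraded) − metric(baseline) with a *paired* design: one
sequence resample per replicate drives both tables, removing shared
cluster noise from the difference. The empirical two-sided p-value is

p = min(1, 2·min(#{Δ* ≥ 0} + 1, #{Δ* ≤ 0} + 1)/(B + 1)),

a +1-corrected formula chosen because it yields exactly p = 1 when every
replicate difference is zero (severity 0) and p ≈ 0.002 at B = 1000 for
effects beyond resampling variation, matching the printed limits of the
protocol it follows. p-values are adjusted by the Holm step-down procedure
(via `stats::p.adjust`), with the multiplicity family defined as all
severity levels within one model-artifact curve, severity 0 included —
m = 9 for blur (so the third-smallest nonzero p gets multiplier 3), m = 8
for shadow, m = 7 for speckle. Replicates on which a metric is undefined
(a resample that lost a class's positives or negatives) are dropped with a
logged warning. Between-model comparisons use the same machinery with
Δ = metric(B) − metric(A).

In simulation (100 clips × 10 frames, per-clip correct-probability drawn
from a Beta with mean 0.7, 500 Monte-Carlo repetitions at B = 500), the
clustered percentile CI covers the population balanced accuracy 95.6% of
the time, inside the 93–97% acceptance band for nominal 95% intervals.

## Degradation curves, failure cases, learning curves

`degradation_curve()` corrupts every test frame at each grid severity,
recomputes predictions and both metric levels, and pairs each severity
against the severity-0 baseline (computed once and reused, so the zero row
is Δ = 0, CI [0, 0], p = 1 *exactly*). Tracked bootstrap metrics default to
frame-level macro-AUC and sequence-level balanced accuracy; other metrics
are reported without CIs to bound runtime. Corruption is applied only to
evaluation inputs, never to training data.

`failure_cases()` extracts units that were classified correctly at
baseline with true-class probability above 0.8 but misclassified after
corruption, reporting the drop in true-class probability
(degraded − baseline). Selection is at sequence level by default (frame
level via `level = "frame"`), since the aggregated probabilities are what a
clip-level user consumes.

`learning_curve()` retrains on stratified sequence-level subsamples
(25/50/75/100% by default) with validation and test fixed, over several
seeds. Subsampling at sequence level (rather than frame level) prevents
leakage between training fractions and the untouched test clips.

## Problem sizes and numerical choices

The test suite exercises the full study-shaped dataset (217 clips, 2170
frames at 256×256) for the dataset-shape, classifier-competence and
speckle-collapse checks, and a reduced fixture (32 clips × 5 frames at
96×96, HOG resize 64) for bootstrap and orchestration tests; bootstrap
depth is B = 1000 where a published identity is asserted and B = 200–500
in property checks. These sizes are the package's choice of desk scale:
large enough that every qualitative finding (chance-level collapse at
speckle σ = 3, monotone macro-AUC decline along curves, CI coverage) is
reproduced, small enough to iterate on a laptop. Ties in argmax break to
the lowest class index; all RNG streams derive from named stage hashes of
one global seed, so any stage can be rerun independently and full runs are
byte-identical.

## Known limitations

Phantom separability makes absolute metrics optimistic; only *relative*
degradation behaviour transfers. The speckle simulator draws independent
pixels, so it understates the spatial correlation of clinical speckle, and
the shadow cone is a single centred attenuator with configurable but
non-random azimuth. The small CNN is a desk-scale stand-in for fine-tuned
pretrained backbones: it preserves the training recipe's structure
(optimizer, scheduling, weighting, early stopping) but not the capacity or
pretraining of an 18/34-layer residual network, and absolute accuracies on
real data would differ accordingly.
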