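---
title: "Curriculum-masked autoencoder pretraining and snapshot ensembles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curriculum-masked autoencoder pretraining and snapshot ensembles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Masked-autoencoder (MAE) pretraining hides a fraction of image patches and
trains an encoder–decoder to reconstruct the hidden pixels. The masking
ratio is the method's most sensitive hyperparameter, and tuning it by
training one model per candidate ratio is expensive. `currimae` implements
the curriculum alternative: a *single* pretraining run whose masking ratio
rises in fixed stages (60%, 70%, 80%, 90% by default), paired with a cyclic
cosine learning-rate schedule that warm-restarts at every stage boundary.
At the end of each stage — one complete learning-rate cycle — a model
snapshot is saved. Each snapshot is then fine-tuned for multi-label
classification, and the fine-tuned snapshots are combined by averaging
their sigmoid scores. The target application is thoracic disease
classification on chest radiographs: pretraining on large unlabeled adult
collections, fine-tuning on a small pediatric set with six disease labels
and roughly 65% "no finding" rows.

Everything runs on one CPU at reduced scale: the Vision-Transformer
encoder/decoder, backpropagation and AdamW are implemented in base R, and a
seeded synthetic radiograph generator stands in for the real datasets, so
the full chain is testable end to end.

## Model

Images are resized, cropped, replicated to three channels, standardized
with ImageNet statistics, and cut into non-overlapping `patch_size ×
patch_size` patches in row-major order (`patchify()`, exactly invertible by
`unpatchify()`). A masking plan draws `round(ratio · n_patches)` patch
indices uniformly without replacement; rounding is half-up so the realized
ratio is the nearest achievable to the nominal one (base R's banker's
rounding would bias alternate cases downward).

The encoder is a pre-norm ViT: linear patch embedding, a class token,
fixed 2-D sinusoidal positional embeddings, and blocks of multi-head
self-attention plus a GELU MLP with residual connections. During
pretraining the encoder consumes *only* the visible tokens (plus the class
token); this is asserted as a property ("encoder blindness") rather than
assumed. The decoder maps encoder outputs to a narrower width, inserts a
shared learnable mask token at every masked grid position, restores
positional embeddings, runs its own (smaller) transformer, and predicts
all patch pixels.

The reconstruction objective is the per-patch masked mean squared error

$$\mathrm{loss} = \frac{1}{|B|}\sum_{i \in B} \lVert X_i - Y_i \rVert_2^2,$$

summed over the masked set \(B\) only and averaged over \(|B|\). Two
readings of "MSE" are possible (with or without an extra division by the
pixels per patch); the literal per-patch form above is implemented, and a
`norm_pix_loss` flag (off by default) optionally standardizes each target
patch first. Visible patches contribute exactly zero, which the test suite
verifies by perturbing predictions at visible indices.

Transformer block weights use Xavier-uniform initialization; the class and
mask tokens and the patch embedding use a truncated normal (sd 0.02).
Positional embeddings are fixed sinusoidal tables by default — the
reference recipe says only that positional embeddings are added, and the
fixed form keeps the parameter count down and the forward pass exactly
reproducible.

The decoder's shape is genuinely open: published parameter counts imply a
decoder of only about half a million parameters, far smaller than common
MAE defaults, but no width/depth is stated. Both are therefore fully
configurable, with defaults (width 256, depth 4) chosen small and a tiny
test preset (width 32, depth 1).

All gradients are hand-derived (layer norm, softmax attention, GELU,
DropPath-scaled residuals, the mask-token scatter) and verified against
central finite differences to ~1e-6 relative error in the test suite.

## Curriculum and learning-rate schedule

A *stage plan* pairs strictly increasing cumulative epoch boundaries with
strictly increasing masking ratios; stage \(k\) covers the 1-based interval
\((b_{k-1}, b_k]\), so "the first 200 epochs" is exactly epochs 1–200.
`fixed_stage_plan(800, c(.6,.7,.8,.9))` gives boundaries 200/400/600/800;
`adaptive_stage_plan()` gives the incremental variant 125/300/525/800
(stage lengths 125, 175, 225, 275, each 50 epochs longer than the last).

The learning rate follows the cyclic cosine warm-restart form

$$\alpha(t) = \frac{\alpha_0}{2}\Bigl(\cos\Bigl(\frac{\pi\,\mathrm{mod}(t-1,\lceil T/M\rceil)}{\lceil T/M\rceil}\Bigr)+1\Bigr)$$

with \(\alpha_0 = 1.5\times10^{-4}\), \(M = 4\) cycles, and \(t\) advancing
per optimizer iteration (\(T\) = epochs × iterations per epoch). Two
design choices deserve note:

* **Stage-aligned cycles for the adaptive plan.** The closed form above
  assumes equal cycles. Snapshots must coincide with cycle ends, so for
  unequal stages each stage is treated as one warm-restart cycle of its own
  length, restarting at \(\alpha_0\); for equal stages this reduces exactly
  to the closed form (tested). Whether the original adaptive experiments
  kept 200-epoch cycles instead is not stated; the stage-aligned reading is
  the one consistent with per-stage snapshots.
* **No warmup during pretraining.** The schedule contains none; warmup
  appears only in fine-tuning.

Snapshots store weights, the configuration echo, stage index, masking
ratio, epoch, optimizer state and the RNG state, which makes pretraining
exactly resumable — resuming after stage 2 reproduces the uninterrupted
run's final weights bit-for-bit (tested).

## Fine-tuning

Each snapshot's encoder is fine-tuned end to end with all patches kept, a
linear head on the class-token output, elementwise sigmoid, and the mean
of per-class binary cross-entropies. The reference configuration is 75
epochs (5 warmup), base rate 2.5e-3, batch 128, AdamW
(\(\beta_1=0.9,\beta_2=0.99\), weight decay 0.05), layer-wise learning-rate
decay 0.55, RandAugment magnitude 6, DropPath 0.2, three repeats with
different seeds. Choices the recipe leaves open, resolved here:

* **Warmup shape**: linear from 0 to the base rate, then cosine decay to 0,
  stepped per iteration.
* **Layer-wise decay mapping**: `layerwise_lr(base, d, k, depth)` =
  `base · d^(depth−k)`; the head and final norm use the base rate, block
  \(k\) gets exponent `depth − k`, and the patch embedding and class token
  (index 0) get the deepest discount.
* **DropPath**: uniform rate 0.2 across blocks (a linear ramp across depth
  is the other common convention; uniform is simpler and the rate is a
  single stated number).
* **RandAugment**: the standard two-ops-per-image policy. The op set keeps
  translations, rotation, brightness, contrast, solarize and posterize;
  hue/color operations are omitted because the inputs are replicated
  grayscale, where they are either inert or meaningless.
* **Weight decay** applies only to genuine weight matrices, not to biases,
  layer-norm parameters or tokens.
* **No gradient clipping** (none is stated).

## Evaluation

Fine-tuned snapshots are scored with deterministic eval-phase
preprocessing (center crop, no flip). The ensemble is the arithmetic mean
of the member score matrices,
\(h_{\mathrm{ensemble}} = \frac{1}{m}\sum_j h_j(x)\), averaged at the
score level *before* thresholding. The decision threshold defaults to 0.5
(a threshold is prescribed but its value is not; it is exposed as a
parameter and CLI flag). Per-class AUC is the rank statistic with midrank
tie handling — equal, by an exhaustive-pair-count property test, to the
fraction of concordant positive–negative pairs with ties counted half.
Sensitivity, precision and F1 come from the thresholded predictions;
zero-denominator cases return 0 with a `degenerate` flag, and a class with
no positives or no negatives reports `NA` AUC rather than being dropped.
Aggregates are support-weighted means,
\(\sum_i w_i m_i / \sum_i w_i\), with \(w_i\) the per-class positive count
in the evaluation split (a multi-label row counts toward every positive
class, so weights can sum past the row count). Accuracy is deliberately
not reported: with ~65% "no finding" rows it is uninformative.

## The synthetic generator

`generate_cxr_like()` emulates just the statistical structure the pipeline
depends on: grayscale thorax-like images (bright body ellipse, darker lung
fields), one localized class-specific pattern per positive label (blob,
streak or checker texture, with geometry a deterministic hash of the class
name so a class looks identical across runs), Gaussian pixel noise, and
multi-label Bernoulli draws with optional multiplicative co-occurrence
odds boosts applied sequentially in class order. Identical specs give
bit-identical batches.

`generate_pedicxr_raw_labels()` produces the raw 15-class pediatric-style
tables that exercise the restructuring rules: about 65% "no finding",
core disease frequencies proportioned like the real table, four classes
with zero test positives, and five classes with 1–19 training positives.
One structural property is enforced rather than left to chance: in the
real table every core class clears the 20-positive merge threshold by a
wide margin (the thinnest has 392 training positives), so at reduced
sample sizes the generator tops up any core class that would otherwise
fall below the threshold. Without this, a scaled-down table could merge a
core class and change the final schema — a property the real data cannot
exhibit.

What the generator does *not* emulate: anatomical realism, pediatric
vs. adult morphology, scanner/exposure variation, label noise, or any
spatial correlation between co-occurring findings. Passing tests therefore
demonstrate that the pipeline's mechanics are correct, not that the method
reaches any particular performance on real radiographs.

## Problem sizes for the CPU-scale presets

The `toy` preset uses 64-pixel images with 8-pixel patches (64 patches), a
64-wide/2-deep encoder with 4 heads, a 32-wide/1-deep decoder, batch 16,
and an 8-epoch curriculum with boundaries 2/4/6/8 — the smallest geometry
that still exercises multi-head attention, multi-block depth and all four
curriculum stages. The pipeline defaults pair this with 128 pretraining
images, 200 raw pediatric training rows and 80 test rows, one fine-tuning
repeat of 6 epochs (1 warmup) per snapshot, and a peak pretraining rate of
1e-3 (the full-scale 1.5e-4 is tuned for batch 256 and hundreds of epochs;
a tiny model on a short horizon trains in a proportionally higher range).
The complete chain — simulate, pretrain, fine-tune four snapshots,
ensemble, report — runs in a few minutes on one CPU.

## Degenerate inputs and numerical conventions

* Masking plans must leave at least one masked and one visible patch;
  ratios outside that range are errors, as is an empty masked set in the
  loss.
* `binarize()` uses ≥, so a score exactly at the threshold is positive.
* Mask counts and split sizes round half-up.
* Sigmoid scores are clipped at 1e-12 inside the BCE to avoid log(0).
* The 80/20 train/validation split is a seeded uniform shuffle without
  stratification or patient grouping (neither is stated for the original
  split); at small n a rare class can land entirely in one side, which
  stratification would prevent — flagged as a limitation, not changed.
* Whether "no finding" may co-occur with disease labels is unconstrained:
  any binary matrix is accepted.

## Known limitations

* The transformer is a faithful but small-scale reimplementation; no GPU,
  no mixed precision, no distributed training. Full-scale runs (303k
  images × 800 epochs) are out of reach by design, so published headline
  metrics are not reproduced here — only the analytic and structural
  guarantees are.
* Exact parameter-count parity with the published profiling table is
  impossible because the decoder geometry is unspecified there.
* RandAugment's op set is a grayscale-safe subset, not the full canonical
  list.
* Score calibration and per-class threshold optimization are out of scope.
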