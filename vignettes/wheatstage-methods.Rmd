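---
title: "Growth-stage classification with multi-scale attention fusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-stage classification with multi-scale attention fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Wheat passes through visually gradual phenological stages. Ground-level RGB
photographs of a field plot taken across a season must be sorted into five
stages — Tillering, Mid Vegetative, Booting, Heading, Milking — even though
adjacent stages differ only in subtle cues: canopy row density, the emergence
of spikes, and the slow green-to-yellow shift of maturation. Field imagery
adds nuisance variation (illumination, viewpoint, wind), and the datasets
this package targets mask everything outside a trapezoidal region of
interest to black. Annotations come in two quality tiers: expert-validated
labels (`label_quality = 2`) and farmer-reported ones (`label_quality = 1`);
only the expert tier is used for modelling, and that tier happens to contain
no stage-1 (Crown Root Initiation) or stage-6 (Anthesis) samples, which is
what reduces the seven annotated stages to a five-class task with the stage
mapping {2, 3, 4, 5, 7} → {0, …, 4}.

## The network

`build_model()` assembles four pieces:

1. **Stem** — 7×7 convolution (stride 2, no bias), batch normalisation,
   ReLU, 3×3/2 max pooling. A 3×256×256 input becomes 64×64×64. The absence
   of a convolution bias is not cosmetic: it is what makes the stem's
   trainable-parameter count exactly 7·7·3·64 + 2·64 = 9,536.
2. **Hierarchical backbone** — standard bottleneck residual stages with the
   ResNet-101 composition (3/4/23/3 blocks, expansion 4, stride-2
   downsampling with projection shortcuts at conv3–conv5). It emits the
   feature pyramid c2…c5 at {64², 32², 16², 8²} with channels
   {256, 512, 1024, 2048}.
3. **Adaptive multi-scale attention fusion (AMSAF)** — the part the package
   exists for; see below.
4. **Classification head** — adaptive average pooling to C×1×1, a
   feature-wise affine normalisation, dropout (rate 0.3), and a linear layer
   to K = 5 logits. The normalisation layer is included because the head's
   published count, 14,341 = (2048·5 + 5) + 2·2048, forces its presence;
   the chosen order is pool → norm → dropout → linear.

### AMSAF

The fusion head runs in five stages, exposed individually as
`align_and_unify()`, `build_global_context()`, `channel_attention()` /
`spatial_attention()`, `csib_refine()` and `wfa_fuse()`:

* **Alignment.** Each pyramid level is downsampled to the deepest level's
  8×8 resolution by area-style average pooling and mapped to the common
  width C = 2048 by a 1×1 convolution + ReLU. Pooling was chosen over a
  named interpolation kernel because it is resolution-agnostic; the deepest
  level also passes through its own learned 1×1 so all four branches are
  learned mappings.
* **Global context.** The four aligned maps are channel-concatenated
  (4C×8×8) and reconciled by a 1×1 convolution + ReLU back to C channels.
  "Stacking fusion" is read as concatenation; a learned 1×1 is the minimal
  reconciliation. This construction was a genuinely open design point.
* **Dual attention.** From the global context, a squeeze-and-excitation
  bottleneck (global average pool → C/16 → ReLU → C → sigmoid) yields one
  channel gate in (0,1) per channel, and a spatial branch (channel-wise
  mean and max maps, stacked, 7×7 convolution, sigmoid) yields one saliency
  value per location. Ratio 16 and kernel 7 are the community defaults; both
  are configurable (`amsaf_config()`).
* **Cross-scale interaction block.** Each aligned scale is multiplied by
  the channel gate (broadcast over space), then by the saliency map
  (broadcast over channels), flattened to h·w = 64 tokens of dimension C,
  and refined by that scale's transformer encoder: one pre-norm layer,
  8 heads, feed-forward width C, GELU, learned positional embeddings of
  length h·w added on entry. Depth, heads and feed-forward width are
  unstated in the source architecture; one minimal layer per scale with
  unshared weights was chosen (unshared is consistent with the large
  published fusion-module parameter count). A single token (h·w = 1) is a
  legal degenerate case.
* **Weighted feature aggregation.** Each refined map passes through a
  dedicated 1×1 convolution to C/2 + ReLU, is globally pooled, the four
  pooled vectors are concatenated (4·C/2) and a linear layer + softmax
  yields one confidence weight per scale — a point on the 4-simplex,
  spatially invariant by construction. The fused feature is the convex
  combination of the **full-width** refined maps; the C/2 branch exists only
  to produce weights. Mean per-batch weights are recorded in the training
  history (`wfa_w1..4`) for inspection.

The published per-module dimension table can pin down the stem and head
exactly, but not the hierarchical module (printed 43,887,872 vs 42,490,624
for the standard composition) or the fusion module (printed 154,788,236 vs
134,856,935 under the choices above). `parameter_audit()` therefore prints
achieved and published values side by side with a match flag and asserts
nothing about the two under-determined rows; `enumerate_param_counts()`
recomputes every row analytically from the declared layer shapes as an
independent cross-check of the engine's counting.

### Ablation variants

`model_config(variant = …)` reproduces the ablation grid around the same
backbone and the exact same head, so metric differences isolate the fusion
machinery: `baseline` (conv5 → head), `channel_attention` (SE gate on
conv5), `spatial_attention` (saliency gate on conv5), `multiscale_fusion`
(aligned pyramid, unweighted mean — FPN-like, no attention, no
transformer), and `amsaf` (full pipeline). Parameter counts increase
strictly along that order.

## Training

`train_model()` minimises cross entropy with AdamW. Defaults follow the
published schedule: learning rate 1e-4, weight decay 1e-4, up to 100
epochs, dropout 0.3, early stopping with patience 20, and learning-rate
decay to 80 % of its current value after 10 consecutive epochs without
improvement of the monitored metric. Decisions the schedule description
leaves open, resolved here: the monitored metric is validation Top-1 (ties
keep the earlier best epoch); both patience counters count epochs since the
last improvement; an LR decay resets only the plateau counter, never the
early-stopping counter; batch size defaults to 32; the validation set, when
not supplied, is a stratified 10 % carve-out of the training split. The
whole schedule is a pure state machine (`simulate_schedule()`) so it can be
verified against hand-written metric sequences without a model.

Initialisation is Kaiming-style from a single configuration seed, with one
deliberate policy: the last batch-norm gain of every bottleneck starts at
zero ("zero-init residual"), making each block identity-like at the start.
Without it the 33-block stack needs far more than a dozen epochs to move at
all; with it the network trains from scratch in minutes at desk scale.
Pretrained weights are intentionally not shipped or downloaded; whether the
original model was ImageNet-pretrained is never stated, so `pretrained`
semantics reduce to the seeded random init.

## Data pipeline

`load_metadata()` enforces the `image_id, stage, label_quality` schema and
collects malformed rows into a rejects report; `filter_expert()` keeps
quality 2 and treats stage 1/6 in the expert tier as a contract violation;
`stratified_split()` implements the 80:20 split per class with round-half-up
rounding (the source protocol states only the global ratio; per-class
rounding makes split sizes reproducible and exact). Augmentation runs
geometric transforms first (rotation ±15°, translation ≤10 %, zoom
0.9–1.1, horizontal flip p = 0.5, region erasure of 2–10 % of the area with
p = 0.5), then photometric ones (grayscale p = 0.1, brightness/contrast/
saturation jitter ±20 %, Gaussian noise σ = 0.02) — the operation list is
fixed by the protocol, the magnitudes are this package's defaults and all
are configurable. Every transform is exactly skipped at magnitude zero, so
the identity configuration returns the input bit-for-bit, and each
augmented sample is reproducible from (master seed, sample seed).

## The synthetic generator

No imagery ships with the package; `synth_dataset()` stands in for field
data with procedurally generated images whose class structure mimics the
three phenological cues: stripe frequency across the image (canopy row
density rises with stage), the number of bright elliptical blobs (spike
emergence), and a green→yellow colour interpolation (maturation). The
per-stage values live in `inst/extdata/synth_class_params.csv`, cover all
seven stages (so farmer-quality rows spanning stages 1–7 can be emitted),
and increase monotonically with stage. Everything is composited inside a
wide-bottom trapezoid whose vertices are jittered ±10 % per image; the
exterior is exactly zero in all channels, mirroring the region-of-interest
masking of the real data. `difficulty` scales additive Gaussian pixel noise
(σ = 0.25·difficulty) and the per-image jitter of the class parameters.

What this emulates — and what it does not: the generator produces
class-separable, ROI-masked imagery with controllable noise, which is
enough to exercise filtering, splitting, augmentation, training dynamics
and the full metric battery end to end. It does not reproduce the
fine-grained inter-stage ambiguity, illumination variation or label noise
of real field photographs, so held-out accuracy on it says nothing
quantitative about accuracy on real data; published full-scale results
(Top-1 ≈ 89 %, AUC ≈ 98 % on the real dataset) require the real imagery
and GPU-scale training and are out of scope here.

## Problem sizes and numerical choices

The test suite and the acceptance script run two regimes, chosen once:

* **Reference widths** (channels 64…2048, 256×256 input) for everything
  that must match published numbers exactly — parameter audits and the
  dimension table of a single forward pass.
* **Tiny widths** (all channels ÷ 8, 64×64 input) for learning dynamics:
  100 synthetic images per class at difficulty 0.25, a stratified 80:20
  split, the baseline variant, AdamW at 3e-3 for 15 epochs with batch 32.
  The 3e-3 rate (rather than the full-scale 1e-4) is deliberate: a small
  model trained from scratch on easy synthetic classes sits in a different
  optimisation regime from a mature 44 M-parameter backbone being
  fine-tuned. Under these conditions held-out Top-1 reaches ≈ 0.95–1.0;
  the suite asserts ≥ 0.90.

Numerical conventions worth knowing: argmax ties resolve to the lowest
class index (quantised scores can tie); per-class metrics return 0 with a
warning on zero denominators; a class absent from both truth and prediction
has OvR accuracy 1; AUC is rank-based with mid-rank ties (identical to
trapezoidal ROC integration), classes with no positives or no negatives are
excluded from macro/weighted averages with a warning; the weighted AUC uses
class frequencies in the evaluated truth vector; softmax and cross entropy
are computed with max-shifting; batch norm uses the biased batch variance
for both normalisation and running statistics (momentum 0.1).

## Known limitations

* The reverse-mode engine is CPU-only and double-precision; reference-width
  training is out of reach (a forward pass alone is ~25 s), which matches
  its role here: audits and shape verification at reference width, learning
  at tiny width.
* `share_tf = TRUE` (one encoder shared across scales) is inference-only;
  the per-scale gradient caches assume unshared encoders.
* The two published parameter counts that cannot be derived from the
  description (hierarchical, fusion) are reported, never matched; treat the
  audit's `match = no` rows as documentation, not failure.
* JPEG/PNG/TIFF decoding is delegated to EBImage; the synthetic generator
  writes PNG.
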