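---
title: "dermshuffle: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dermshuffle: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dermshuffle)
```

## The classification problem

Dermoscopy produces standardized RGB images of pigmented skin lesions
(PSLs). The clinically relevant taxonomy used here has seven classes —
AK, BCC, BKL, DF, MEL, NV, VASC — and the public archives that carry them
are strongly imbalanced: melanocytic nevi outnumber dermatofibromas by a
factor of thirty. dermshuffle implements a lightweight convolutional
classifier for this task together with the surrounding machinery
(balancing augmentation, stratified cross-validation, one-vs-rest
metrics, Grad-CAM saliency), sized so that every component runs and
trains on a single CPU.

## Architecture

The backbone follows the ShuffleNet-v2 design idiom: cheap grouped
computation plus an explicit channel permutation to restore cross-group
information flow.

**Channel shuffle.** For `C` channels in `G` groups of `N = C/G`, the
channel index list is reshaped to a `(G, N)` matrix, transposed, and
flattened: output channel `j` reads input channel `(j mod G)·N + ⌊j/G⌋`.
This is a bijection — `channel_shuffle(channel_shuffle(x, G), N)` is the
identity — and involves no arithmetic on activations.

**Shuffle unit** (`stride 1`, even width). An even channel split; the
identity branch passes through; the transform branch applies
`1×1 conv + BN + ReLU`, `3×3 depthwise conv + BN`, `1×1 conv + BN + GELU`;
concatenation; channel shuffle with `G = 2`. The split ratio is the even
half-split; the closing shuffle has exactly two groups because exactly two
branches are concatenated. A unit at width `C` holds
`2·(C/2)² + 9·(C/2) + 3·C` parameters (two pointwise convolutions, one
depthwise kernel, three BN scale/shift pairs).

**Squeeze-and-excitation.** Global average pooling squeezes `W×H×C` to
`1×1×C`; the excitation bottleneck maps `C → max(1, ⌊C/r⌋) → C` with GELU
between the two fully connected layers and a sigmoid last, so every gate
lies strictly in (0, 1); the input map is rescaled channelwise. The
ordering (GELU inside, sigmoid last) is the standard SE construction and
the one consistent with gates bounded in (0, 1); `r = 16` by default.

**Network assembly.** A 3×3 stride-1 stem (24 channels, BN, ReLU) with a
1×1 expansion into stage 1; four stages of widths 64/128/256/512 repeated
3/7/10/9 times; an SE block and a 2×2 stride-2 max pool after each stage;
1×1 conv + BN + GELU expansions between stages (width growth needs *some*
mechanism; a pointwise expansion is the minimal standard one); global
average pooling; `linear(512→128) + GELU + linear(128→7)` with softmax at
inference. All downsampling comes from the four pools, so inputs must be
divisible by 16 (256 → 16×16 before the global pool). Training operates on
logits with categorical cross-entropy, which is mathematically identical
to softmax + log-loss but numerically stable.

**Parameter budget.** The canonical configuration counts 1,920,027
trainable scalars — 1.9 M at one decimal. Convolutions followed by BN are
biasless (the BN shift makes a conv bias redundant), and BN contributes
2 parameters per channel; both conventions are pinned because the budget
is an acceptance surface. The per-stage repeats (3, 7, 10, 9) and head
width 128 were chosen once so the total lands in the 1.85–1.95 M window;
`calibrate_budget()` is the documented, deterministic repair rule for
configurations that drift out of it (stage-4 repeats first, then head
width). Its search covers repeat offsets up to ±3 so that, e.g., a
configuration two repeats over budget is repaired back rather than
rejected.

**FLOPs** are not reported as an acceptance surface: a floating-point
count is only meaningful relative to a counting convention (multiply
versus multiply-accumulate, BN folding, input size), and no convention
reproduces a unique published figure consistently with a 1.9 M-parameter
float32 model. `count_parameters()` reports the exact scalar count
instead.

## Data pipeline

Images are bilinearly resized to 256×256×3 and rescaled by 1/255.
Region-of-interest selection exploits the fact that lesions are darker
than surrounding skin: the crop is the largest square centered on the
intensity-weighted centroid of (1 − normalized grayscale) that fits in
the image, never smaller than half the short side; uniform images fall
back to the geometric center. This centroid rule is a documented stand-in
for an unspecified automatic ROI procedure and is validated on synthetic
discs with known centers.

The balancing engine brings every class to exactly 4000 active records
(28,000 over seven classes). Deficit classes keep all originals and add
augmented copies round-robin over the originals, each with an
independently sampled transform: rotation U(−30°, 30°), brightness
U(0.9, 1.1), zoom U(0.9, 1.1), shear U(−0.1, 0.1), horizontal and
vertical flips Bernoulli(0.5), and Gaussian pixel noise with per-image σ
drawn U(0, 0.45) on the [0, 1] scale (the single printed noise number is
read as the upper bound of that draw; the top of the range is visually
harsh, which is why σ is sampled per image rather than fixed). Geometric
parameters printed as single numbers (30°, 0.1) are read as symmetric
ranges, the conventional single-number augmentation notation. Surplus
classes (NV: 6000 → 4000) are subsampled without replacement under the
run seed; dropped records stay in the manifest as `downsampled-out` so
the operation is auditable and idempotent. Every augmented record stores
its full sampled parameters (including a dedicated noise seed) in
`transform_json`, so `replay_augmented()` reproduces its pixels
bit-identically.

## Synthetic data generator

`generate_image()` emulates just enough structure for every module to be
exercised honestly: a skin-toned background with illumination gradient
and grain, plus one lesion — a rotated ellipse with a sinusoidally
perturbed border, class-specific color, texture frequency, and optional
darker globule dots — occupying 8–35% of the frame at a random
off-center position. The seven color/shape/texture parameter sets are
pairwise distinct, lesions are always darker than skin (so ROI selection
has signal), and the binary mask is returned with the image. Default test
resolution is 64×64; 256 is supported. What the generator does *not*
emulate: dermoscopy artifacts (hairs, rulers, gel bubbles), intra-class
morphology families, or the inter-class visual ambiguity of real
archives. Tests passing on this generator therefore demonstrate that the
implementation is correct and trainable, not that real-archive accuracy
transfers.

## Training harness

Defaults: SGD with momentum 0.9 and weight decay 5×10⁻⁴ (the printed
exponent-free value is read as the conventional 5e-4; 5e+4 would destroy
training), base learning rate 0.001, step decay ×0.5 every 10 epochs
(four decays across the 40-epoch default; the decay period is not pinned
by any published number and is configurable), batch 64, 10-fold
stratified cross-validation. Adam, RMSprop, AdaMax, Adadelta and Nadam
are available as alternatives; SGD is the default choice. Everything is
seeded — initialization, shuffling order, augmentation — and training is
bit-reproducible on CPU. Folds are split *before* any augmentation, so no
augmented sibling of a test image can leak into its training fold; the
reference protocol is silent on this ordering and the leakage-safe order
is adopted.

Desk-scale problem sizes used by the test suite: the learnability check
trains a reduced-width configuration (stem 4, widths 4/8/16/32, one unit
per stage, SE reduction 4, head 32 — 4096 parameters) for 15 epochs at
learning rate 0.01 on 100 synthetic images per class at 64×64, reaching
≈98% training accuracy in about three minutes; the balancing check runs
the full 14,000 → 28,000 pipeline at 64×64. The higher learning rate for
the reduced model is the usual scaling when a network is three orders of
magnitude smaller than the canonical one; the canonical defaults above
are unchanged.

## Metrics

`binarize()` reduces the 7×7 confusion matrix one-vs-rest; accuracy,
sensitivity, specificity and precision are reported ×100, F1 on the
fractional scale (F1 is scale-consistent only if precision and recall
enter as fractions; a percent view is exported alongside), and MCC in
[−1, 1] (equal, for binary indicators, to the Pearson correlation of
truth and prediction — the identity the test suite uses as an independent
oracle). Ratios with zero denominators — classes absent from a fold — are
reported as 0 with a warning, keeping macro averages defined; macro
averaging is the unweighted mean over the seven classes, and overall
accuracy (trace/total) is reported separately.

## Grad-CAM

The saliency map for class *k* backpropagates the class-*k* logit to the
stage-4 SE output (the last spatial map before pooling — the deepest,
most class-specific tap; the tap is configurable), averages the gradient
spatially into per-channel weights, takes the ReLU of the weighted
channel sum, upsamples bilinearly to the input size, and min–max
normalizes to [0, 1] (identically zero maps stay zero, rather than
dividing by zero). Backpropagation through BN in evaluation mode treats
the running statistics as constants. On the synthetic task the heatmap
mass centroid is required by the test suite to fall inside the lesion
bounding box for at least 80% of 50 held-out images after the reduced
training run.

## Numerical choices and degenerate inputs

* GELU is the exact form `x·Φ(x)` (not the tanh approximation); its
  derivative uses the cached CDF.
* BN uses population variance within the batch, ε = 1e-5, running-stat
  momentum 0.1.
* Max pooling breaks ties toward the first element in column-major scan
  order, making the backward scatter deterministic.
* Softmax subtracts the column maximum; cross-entropy clips probabilities
  at 1e-12; a non-finite loss aborts training with a diagnostic rather
  than continuing silently.
* Channel counts that do not divide the group count, odd unit widths,
  empty classes, unknown Grad-CAM taps and non-RGB inputs all raise
  immediate, named errors.

## Known limitations

The headline accuracies published for this model family on HAM10000/ISIC
(≈99% with GPU-scale training on 28,000 real images) are outside what a
CPU-scale synthetic benchmark can or should claim; this package verifies
architecture, counts, pipeline semantics and trainability instead.
ImageNet-pretrained initialization is supported only as a
checkpoint-loading hook (`load_checkpoint()`); no pretrained weights ship
with the package. Inference speed was not optimized beyond what correct
C++ kernels provide.
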