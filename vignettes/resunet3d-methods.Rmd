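---
title: "Methods: residual 3D U-Nets with deep supervision for multi-region tumor segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residual 3D U-Nets with deep supervision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The segmentation problem

Gliomas are delineated on multi-modal MRI (T1, contrast-enhanced T1, T2,
FLAIR) with a four-value voxel vocabulary: 0 background, 1 necrotic and
non-enhancing tumor core (NCR), 2 peritumoral edema (ED), 4 enhancing tumor
(ET). Evaluation, however, scores three *overlapping* regions:

* **WT** (whole tumor) = {1, 2, 4},
* **TC** (tumor core) = {1, 4},
* **ET** (enhancing tumor) = {4},

nested as ET ⊆ TC ⊆ WT. `labels_to_regions()` encodes a label volume as
three binary channels in this order, and the network predicts the three
regions directly through independent sigmoid channels rather than mutually
exclusive softmax classes. This is the representation the loss, the
post-processing, and the Dice reports all share.

## Architectures

`network_config()` describes four encoder–decoder variants built from a
common block: 3×3×3 convolution (stride 1 or 2), instance normalization,
leaky ReLU with slope 0.01. Downsampling is by stride-2 convolution;
each decoder stage applies a 2×2×2 transposed convolution (stride 2),
concatenates the same-level encoder skip, and applies a stride-1 block.
Channels double per level from `base_channels` and are capped at
`channel_cap`; the default depth-7, 64→512 schedule is
`64, 128, 256, 512, 512, 512, 512`, and a depth-6 encoder with base 32 and
cap 320 reproduces the smaller 32→320 baseline. A 128³ input at depth 7
reaches a 2×2×2 bottleneck.

* `unet` — the plain variant.
* `res_unet` — every block is wrapped with an identity shortcut; when the
  channel count or spatial stride changes, the shortcut is a 1×1×1
  (optionally strided) projection. This is the only difference from
  `unet`, and both emit identical output shapes.
* `attention_unet` — each skip is reweighted by an additive attention
  gate: α = σ(ψ(LReLU(Wₓ·skip + up(W_g·gating)))), with the gating signal
  taken from the coarser decoder level, inter-channel width half the skip
  channels, and α ∈ (0,1) broadcast over the skip channels.
* `ae_unet` — the residual network plus a variational-autoencoder branch
  on the bottleneck: a 1×1×1 reduction to 16 channels, dense layers to a
  256-dimensional latent (μ, log σ²), reparameterized sampling
  z = μ + exp(log σ²/2)·ε, and a mirrored transposed-convolution decoder
  that reconstructs the input as a regularizer. The 16-channel reduction
  before the dense layers is a deliberate sizing choice: it keeps the
  dense parameter count bounded for any input extent. Because the dense
  layers fix the flattened size, `input_size` is part of the
  configuration for this variant.

**Deep supervision.** With `deep_supervision = TRUE`, 1×1×1 + sigmoid
output heads are attached to the last `n_heads = min(3, depth − 1)`
decoder levels: head A = 1 is the full-resolution output, A = 2 and A = 3
sit at 1/2 and 1/4 resolution. Their targets are the full-resolution
region masks quantized by nearest-neighbor sampling
(`downsample_regions_nn()`, anchored at index 0 with source index
⌊i·factor⌋), which preserves binary values and region nesting exactly.

Inputs whose extent is not divisible by 2^(depth−1) are zero-padded
symmetrically and every head is cropped back
(head A to ⌈extent/2^(A−1)⌉). An optional fifth input channel
(`foreground_channel()`) marks voxels where any modality is nonzero —
skull-stripped MRI has exact-zero background, so this flags the brain
support.

## Losses

`loss_config()` controls a composite loss:

* **Batch Dice** per region channel:
  1 − (2Σpt + s)/(Σp + Σt + s), with the sums pooled over *all items of
  the batch* jointly (per-item averaging is available via
  `batch_dice = FALSE`); the channel mean is reported. The stabilizer
  s = 1e-5 keeps empty channels finite.
* **Secondary term**: binary cross-entropy, or focal loss
  −(1−p_t)^γ log p_t with γ = 2 by default; γ = 0 recovers BCE exactly.
  Probabilities are clamped to [1e-7, 1 − 1e-7] before the logarithm.
* **Composite**: α·Dice + (1−α)·secondary with α = 0.7, the optimum of a
  0.5–0.8 sweep. α multiplies the Dice term.
* **Deep supervision**: the normalized weighted sum
  Σ w_A·L_A / Σ w_A over heads, equal weights by default. Weights
  (w, 0, 0) reduce it to the final head; a single head reduces it to the
  composite loss.
* **Autoencoder regularizer** (`ae_unet`): mean squared reconstruction
  error plus the closed-form KL divergence of N(μ, diag e^{logσ²}) from
  N(0, I), weighted 0.1 each by default (the weights are exposed; no
  canonical value exists for this setup).

The losses are implemented once, over the package's own reverse-mode
autodifferentiation tape, and the exported array API evaluates the same
graph — so the quantities reported during training are the quantities the
tests verify against brute-force oracles.

## Training

`train_model()` optimizes with Adam (lr 1e-4, weight decay 1e-5 applied
to convolution and dense weight matrices), batch size 2, patch size 128³
at full scale (any extent divisible by 2^(depth−1) works; the test-scale
studies use 32³). Patches are foreground-biased: with probability
`fg_bias` (0.5) the patch is centered on a uniformly drawn tumor voxel.
This sampling policy is an extension knob — unbiased sampling on sparse
tumors starves the Dice gradient. There is no training-time intensity or
spatial augmentation; augmentation exists only as test-time flips at
inference.

The validation loss (on a held-out 20% by default, or an explicit fold)
drives a reduce-on-plateau schedule (factor 0.5, patience 5, floor 1e-6 —
values chosen here, as only the scheduler family is prescribed) and early
stopping with patience 10: training stops once 10 consecutive epochs fail
to improve on the best validation loss, and the best-validation parameters
are returned. `make_folds()` provides deterministic k-fold splits
(default k = 5; a 3-fold variant is equally legitimate for tuning and is
one flag away). Runs are exactly reproducible given (seed, configs,
dataset); histories record per-head losses (L1, L2, L3), the total, the
validation loss and the learning rate per epoch.

Numerical notes: a non-finite training loss aborts with a diagnostic
rather than continuing; the backward sweep releases intermediate buffers
as soon as they are consumed, and validation forward passes are detached
to plain arrays, which bounds peak memory near a single training step.

## Inference

`plan_windows()` tiles a volume with patches overlapping by exactly half
a patch per axis; the final window per axis is clamped to end at the
volume boundary, so every voxel is covered and no synthetic margin is
predicted. Overlapping predictions are combined as an importance-weighted
mean: the weight map is a Gaussian centered on the patch with
σ = extent/8 per axis, floored at 1e-3 so all weights stay positive
(center voxels count more than window borders; the functional form is
this package's choice). The normalization is exact: a constant-output
network reproduces its constant to machine precision under any overlap.

`tta_predict()` averages the probabilities of the eight axis-flip
variants (flip subsets of {x, y, z}, identity included), un-flipping each
prediction before averaging. `predict_volume()` wires both together for a
trained checkpoint, appending the foreground channel when the network
expects five input channels.

## Post-processing

`postprocess_labels()` maps region probabilities back to labels through a
voxel-wise cascade with strict comparisons: WT < 0.45 → background,
else TC < 0.40 → ED (2), else ET < 0.45 → NCR (1), else ET (4). Two
enhancing-tumor clean-up stages follow, per-component first and then
global, because the two rules address different granularities:

1. every ET connected component (26-connectivity by default; 6 and 18
   available) with fewer than 16 voxels *and* mean ET probability below
   0.9 is relabeled NCR;
2. if fewer than 73 ET voxels remain in total and their mean probability
   is below 0.9, all ET becomes NCR.

Both stages only ever remove ET, and component filtering is idempotent.
The "mean likelihood" reading (component mean rather than per-voxel
probability) is used for both rules. The companion metric convention:
when an ET mask is empty in both prediction and reference the Dice score
is 1, and 0 when only one is empty. `dice_score()` applies this
convention to all three regions uniformly — stated for ET in the source
material, but applying it uniformly keeps the metric total; the report
lists regions separately so the choice is visible.

## The phantom generator

`phantom_config()`/`generate_case()` produce fully synthetic cases so the
entire pipeline is exercisable without any dataset download: a spherical
"brain" of nonzero intensity on exact-zero background carrying three
concentric tumor ellipsoids (ET inside TC inside WT, realized as labels
4/1/2), per-case jitter on center and radii, four modality channels with
distinct but partially redundant tissue contrasts, and i.i.d. Gaussian
noise (σ = 0.05 on intensities of order 0.3–0.95) inside the brain mask.
Default radii scale with the volume (13/8/4 voxels at 64³). Every case is
a pure function of (seed, case index), and `generate_dataset()` writes
NIfTI files plus a manifest that regenerates them bit-identically.

What the phantom does *not* emulate: MRI physics (bias fields, partial
volume, anisotropic voxels), anatomical variability, multifocal or
non-ellipsoidal tumors, and inter-rater label noise. A model passing the
phantom studies is demonstrably able to learn nested region structure
from multi-channel contrast — no more. Claims about performance on real
BraTS-scale data are deliberately out of scope.

## Study sizes used by the automated checks

The package's own test studies are scaled to a single CPU:

* learnability: 20 phantoms at 48³ (radii 13/8/4), `res_unet` depth 4
  with 8 base channels, 32³ patches, batch 2, Adam 1e-4, α = 0.7
  Dice + focal, 16 training / 4 held-out cases, 30 epochs at 8 steps per
  epoch; held-out whole-tumor Dice is required to reach 0.80.
* deep-supervision comparison: the same data and network, 6 epochs at 4
  steps per epoch, five seeds, comparing final training loss with and
  without auxiliary heads.
* architecture sweep: all four variants, depths 3–7, supervision on and
  off, on 32³ inputs with a reduced channel schedule.

## Known limitations

* The network core is a compact CPU implementation (im2col convolutions
  on a reverse-mode tape); it is exact but not competitive with GPU
  frameworks in throughput, and full 128³/depth-7/512-channel training is
  out of reach on a desktop CPU even though the configuration constructs
  and runs.
* `ae_unet` fixes the input extent at configuration time through its
  dense layers.
* Morphological refinement (dilation/erosion) beyond the two stated ET
  rules is not implemented; no parameters exist for it in the source
  material.
* Fold-level model ensembling is intentionally absent — scores are
  averaged across folds, not predictions.
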