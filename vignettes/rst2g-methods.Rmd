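---
title: "Residual-guided spatiotemporal graph segmentation of DCE-MRI: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual-guided spatiotemporal graph segmentation of DCE-MRI: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Dynamic contrast-enhanced MRI (DCE-MRI) acquires a pre-contrast volume and
one or more post-contrast volumes after injection of a gadolinium agent.
Breast tumors enhance preferentially, so the *residual image* — the
voxel-wise difference between a post-contrast and the pre-contrast volume —
concentrates exactly the kinetic signal a radiologist uses to delineate
lesions. `rst2g` implements a segmentation network that consumes all three
channels (pre, post, residual) per 2D slice and fuses them along four axes:

1. **Weight-sharing hybrid encoder.** A stem convolution block and a chain of
   DownBlocks (2×2 max pooling, two conv+BN+ReLU blocks, a 1×1-projected
   shortcut) extract local features; at the bottleneck the feature map is
   flattened into a raster-ordered token sequence and passed through pre-norm
   transformer blocks whose multi-head self-attention
   $\mathrm{softmax}(Q_h K_h^\top / \sqrt{d_k})\,V_h$ models global context.
   One parameter set serves all three branches, which regularises training
   and forces the network to encode anatomy consistently across phases.
2. **Residual-guided multi-scale refinement (MSR).** At every encoder level
   the three modality features pass through modality-specific 3×3
   conv+BN+ReLU transforms, are concatenated, fused by a channel-wise MLP
   (two 1×1 convolutions, $3C \to C \to C$, ReLU between), and recalibrated by
   a one-channel sigmoid spatial-attention map:
   $F_{out} = F_{fused} \odot \sigma(\mathrm{Conv}_{1\times1}(F_{fused}))$.
3. **Spatiotemporal graph enhancement (STGE).** Per modality, inter-slice
   attention (ISA) applies a modality-specific conv transform, flattens the
   bottleneck into $N = H'W'$ fully connected graph nodes, and runs one graph
   attention layer,
   $\alpha_{ij} = \mathrm{softmax}_j\,\mathrm{LeakyReLU}(a^\top[Wh_i \,\|\, Wh_j])$,
   $h_i^{out} = \mathrm{ELU}(\sum_j \alpha_{ij} W h_j)$, followed by a
   batch-wise slice recalibration (the batch axis is a stack of adjacent
   slices of one patient). Inter-temporal attention (ITA) then fuses the three
   enhanced maps channel-wise with the same MLP + sigmoid-gating pattern as
   MSR.
4. **Decoder.** A U-Net-style chain of bilinear 2× upsampling, concatenation
   with the fused (MSR) skip of the level above, and two conv blocks; a final
   1×1 convolution yields one logit per pixel, and
   $\mathrm{mask} = (\sigma(\mathrm{logit}) \ge \tau)$ with $\tau = 0.5$,
   ties to foreground.

Training minimises the hybrid objective

$$L \;=\; L_{Dice} \;+\; \lambda\, L_{BCE} \;+\; \beta\, L_{Boundary},$$

with $L_{Dice} = 1 - (2\sum_i p_i g_i + \epsilon)/(\sum_i p_i + \sum_i g_i +
\epsilon)$, the mean binary cross-entropy, and a boundary term: the mean L1
difference between the two directional Sobel gradient maps of prediction and
target. Evaluation reports the Dice similarity coefficient
$2|P \cap G|/(|P|+|G|)$, the Jaccard index $|P \cap G|/|P \cup G|$ and the
relative volume difference $(|P|-|G|)/|G|$.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `lambda` | 0.5 | weight of the BCE term (dimensionless, in [0, 1]) |
| `beta` | 0.2 | weight of the boundary term (dimensionless, in [0, 1]) |
| `learning_rate` | 1e-3 | Adam step size |
| `weight_decay` | 1e-4 | L2 coefficient added to the gradient |
| `batch_size` | 4 | consecutive slices per batch (one patient per batch) |
| `n_vit_layers` | 6 | transformer depth at the bottleneck |
| `n_heads` | 4 | attention heads (must divide the bottleneck width) |
| `n_stages` / `channels` | 4 / 32-64-128-256 | encoder depth and widths |
| `threshold` | 0.5 | probability cut for the binary mask (ties → tumor) |
| `k` / `test_frac` | 5 / 0.3 | stratified folds and patient-level test hold-out |

`lambda`, `beta`, the optimizer settings, the batch size, the transformer
depth/heads and the 5-fold / 70-30 protocol are the published operating
point; the encoder depth and channel widths are not specified there, so they
are exposed in `encoder_config()` with defaults sized for the data the model
targets (60-slice, 256×256 volumes). `rst2g_tiny_config()` (2 stages, 16
base channels, 1 transformer layer, 32×32 slices) is the configuration the
test suite trains on CPU. No data augmentation is applied anywhere.

## Decisions where the design was open

* **Which post-contrast phase feeds the residual.** Multi-phase studies do
  not come with a canonical choice; the package uses the *first* (earliest
  enhancement) phase by default and exposes `phase_index_used`.
* **Intensity normalisation.** Per-volume min–max scaling to [0, 1], applied
  to pre and post *before* subtraction, so residuals lie in [−1, 1] and the
  network sees a scanner-independent range.
* **ViT placement.** Transformer blocks sit only at the deepest stage, where
  $N = H'W' \le 256$ keeps dense self-attention tractable; a learned additive
  positional embedding (toggleable) precedes the first block. Pre-norm
  layout with a GELU MLP of ratio 4 follows the standard ViT convention.
* **MSR routing.** One MSR instance per encoder level. The shallow refined
  maps become the decoder skips; at the bottleneck the refined map is summed
  with the ITA output, so both the multi-scale fusion and the graph
  enhancement contribute to what the decoder sees, and the "no STGE"
  ablation reduces exactly to "bottleneck MSR straight to the decoder".
* **ISA inputs.** The three ISA branches read the encoder bottleneck features
  of their own modality (not the fused map), keeping the modality-specific
  graph semantics.
* **GAT conventions.** One dense single-head GAT layer with $C' = C$,
  LeakyReLU slope 0.2 and ELU output nonlinearity — the graph-attention
  literature's defaults, adopted where the architecture leaves them open.
* **Batch-slice attention layout.** The tensor is permuted/reshaped to a
  (B·H, C, 1, W) layout before the 1×1 conv + sigmoid gate; a 1×1
  convolution is position-independent, so the layout choice only affects
  bookkeeping — it is isolated in `batch_slice_attention()` so it can be
  swapped wholesale.
* **Ablation "without local features".** Spatial reduction must survive
  removing the conv path, so pooling is kept and every encoder convolution
  becomes a 1×1 projection.
* **Decoder.** The decoder is unconstrained by the architecture description
  beyond "progressively upsamples"; the U-Net mirror with fused skips is the
  segmentation-field standard and matches the encoder–decoder silhouette.
* **Grad-CAM adaptation.** The scalar score is the sum of logits inside the
  predicted mask (all logits if the prediction is empty); the target layer
  defaults to the deepest conv-stage output ("bottleneck").
* **Split protocol.** A 30 % patient-level test hold-out plus stratified
  5-fold partitioning of the remainder reconciles the two stated protocols
  (70/30 split and 5-fold CV); the stratification variable is the tumor
  volume quantile, the only patient-level covariate every cohort has.
* **Early stopping** on fold-validation Dice (patience 10) selects the
  checkpoint when validation studies are supplied; otherwise the final model
  is kept.

## Batch normalisation under weight sharing

Batch-norm *weights* (scale/shift) are shared across the three branches like
every other encoder parameter, but the *running statistics* are buffers, not
weights: the package keeps one running mean/variance per branch. With a
single shared buffer, the last-encoded branch would overwrite the statistics
of the other two and eval-mode inference could not reproduce training-mode
normalisation. Two further choices follow the same logic: running variances
are stored biased (matching the batch statistics used during training), and
after training — and before any validation scoring — the running statistics
are recalibrated by an exact averaging pass over the training batches
("precise BN"). With these three choices an overfit network's eval-mode
output equals its train-mode output to machine precision, which the test
suite asserts.

## The phantom generator

`phantom_spec()` / `generate_phantom()` synthesise a study as: a smooth
textured background (Gaussian field, low-pass filtered with a 3-voxel
kernel, scaled to sd 0.05 around level 0.35), an ellipsoidal tumor whose
post-contrast intensity is `pre * (1 + enhancement_factor)` against a mild
`background_enhancement`, and independent additive Gaussian noise on the pre
and post acquisitions (so residual noise has variance $2\sigma^2$). Default
geometry mirrors the target data (60 slices of 256×256); cohorts draw tumor
radii, enhancement and noise per patient from stated ranges so tumor volume
varies enough for stratified splitting. Enhancement factors near 1 (tumors
roughly doubling at peak), 5–15 % parenchymal enhancement and noise sd
around 0.02 on a [0, 1]-scaled background are realistic operating values for
breast DCE.

What the phantom does *not* emulate: pharmacokinetic (Tofts-type) washout
curves, coil/bias-field inhomogeneity, motion between phases, multi-focal
disease, and the anatomical complexity of fibroglandular tissue. Passing the
phantom-based tests therefore demonstrates that the architecture, losses,
training loop and bookkeeping are correct and that the model can learn
contrast-driven segmentation; it does not certify clinical performance,
which requires the real cohorts the method was designed for.

## Numerical choices and degenerate inputs

* Dice stabiliser $\epsilon = 10^{-6}$; empty-vs-empty Dice loss is exactly 0.
* BCE probabilities clamped to $[10^{-7}, 1-10^{-7}]$.
* Evaluation metrics on two empty masks: DSC = JI = 1 (perfect agreement);
  RVD on an empty ground truth is an error, and such studies are skipped
  with a warning during evaluation.
* The relative volume difference is reported as the dimensionless ratio
  defined above, not in voxel units.
* Constant volumes min–max-normalise to all zeros; residuals of constant
  inputs are zero.
* A final short slice window is padded by edge-slice replication; padding is
  recorded and dropped at stitching. Batches never mix patients.
* Max-pooling ties route the gradient to the first matching element in a
  fixed scan order; mask thresholding sends ties to foreground.
* All attention rows are checked to sum to 1 within $10^{-6}$.

## Problem sizes used by the tests

The suite trains the tiny configuration on 32×32 phantom slices: a
single-batch overfit (300 Adam steps) and a 10-phantom cohort
(8 slices each, 30 % held out, 12 epochs). These sizes were chosen so the
whole cycle runs on one CPU core in minutes while leaving the learning
dynamics (loss decrease, generalisation across patients, Grad-CAM
localisation) observable. The oracle-equivalence tests run on 2×2-spatial /
≤4-node instances where brute-force reference implementations are exact.

## Known limitations

* Slices are processed as 2D images with the batch axis standing in for the
  through-plane neighbourhood; true 3D (or 3D+time) convolution is a
  different design and is not implemented.
* Dense graph attention over $N$ bottleneck nodes is $O(N^2)$; the
  implementation assumes $N \le 256$ (input 256×256 with 4 stages).
* The engine targets CPU-scale experiments; there is no GPU path, no mixed
  precision and no distributed training.
* Checkpoints store plain R objects and are not portable to other
  frameworks.
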