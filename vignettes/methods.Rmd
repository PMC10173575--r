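---
title: "Methods: 2.5D cascaded attention U-Net segmentation of renal CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 2.5D cascaded attention U-Net segmentation of renal CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nephroseg)
```

# The problem and the model

Kidney tumors and cysts occupy a small fraction of an abdominal CT volume.
Fully 3D convolutional networks capture through-plane context but are
memory-hungry; plain 2D networks are cheap but blind across slices. The
2.5D compromise implemented here feeds the network `k` adjacent axial
slices as channels and predicts the mask of the middle slice only; a volume
is segmented by sliding over all slices and reassembling. `k` is odd
(3 by default, 5 supported); with `k = 1` the model degenerates to plain 2D.

Segmentation is cascaded: a *coarse* network solves kidney-vs-background on
whole slices, the bounding box of the coarse mask (plus margin) is cropped,
and a *fine* network classifies kidney/tumor(/cyst) inside the crop, where
the lesions occupy a usable fraction of the field of view. Final labels are
the fine predictions pasted back into the full volume.

## The residual-sum feature block

Each feature block applies a 1×1 convolution that sets the channel width,
then two additive residual units (3×3 convolution, batch normalization,
ReLU, plus identity), and returns the **sum of both units' outputs**:

\[
x_0 = W_{1\times1} x,\quad
x_1 = \mathrm{ReLU}(\mathrm{BN}(W_1 x_0)) + x_0,\quad
x_2 = \mathrm{ReLU}(\mathrm{BN}(W_2 x_1)) + x_1,\quad
y = x_1 + x_2 .
\]

The final sum (rather than returning \(x_2\) alone) is the block's defining
feature; with the residual branches zeroed the block reduces exactly to
\(y = 2 W_{1\times1} x\), which the test suite asserts analytically. A
`block_type = "plain"` toggle (two ordinary conv+BN+ReLU layers) provides
the ablation baseline.

## Dual-path encoder/decoder and multi-level fusion

The encoder runs two streams. Path 1 is the usual block / 2×2-max-pool
ladder. Path 2 max-pools the **raw input stack** at every level and
concatenates it with the pooled path-1 features to form the next block's
input, so each level sees both learned features and unprocessed intensity
context. Channel widths double per level (`base_width · 2^level`, capped at
512).

The decoder mirrors this. At each level the running "fused" tensor is
bilinearly upsampled 2×; one copy passes a 1×1 channel-setting convolution,
is concatenated with the (attention-gated) skip feature and refined by a
block; the other copy is concatenated unchanged with the block output. The
fused tensor therefore accumulates one width per level, and the final 1×1
classification head sees features from **every** resolution — a
multi-level feature-fusion head. The design was genuinely open on one point — whether the second decoder
path carries the bottleneck or the running fused output — and this
implementation carries the fused output: it is the only wiring in which
spatial extents stay consistent at every level, and it is recorded here as
a design choice.

## Attention-gated skip connections

A skip feature \(x^l\) (extent \(2s\)) is gated by decoder context \(g\)
(extent \(s\)): \(A = W_g g\), \(B = W_x \,\mathrm{avgpool}_2(x^l)\) (both
1×1 projections to a shared width, half the skip's channels),
\(C = A + B\), \(D = \mathrm{ReLU}(C)\), \(E = \psi(D)\) (1×1 to one
channel), \(F = \sigma(E)\), and \(\alpha\) = bilinear upsampling of \(F\)
back to \(x^l\)'s extent; the output is \(\alpha \odot x^l\). Zeroed gate
parameters give \(F \equiv 0.5\), i.e. a constant half-scaling — an exact
neutrality property the tests rely on. Average pooling (not max) is used on
the \(x^l\) branch so the gate's gradient spreads over all four pooled
pixels; the choice is internal to the gate and invisible to its contract.

# Training

* **Loss** (a package default; the task literature uses many variants): voxel-wise
  cross-entropy plus soft multi-class Dice over the foreground classes with
  +1 smoothing, matching the evaluation Dice. Selectable via `loss_name`.
* **Optimizer**: Adam, learning rate 1e-3, no schedule. All gradients are
  hand-derived; a finite-difference check in the test suite verifies the
  full network backward pass to ~1e-10 relative error.
* **Schedule**: up to 100 epochs with early stopping after 30 consecutive
  epochs without monitor improvement (both configurable). "Improvement"
  means exceeding the best value so far by at least `min_delta = 1e-5`,
  which makes the rule deterministic; the rule is factored into
  `run_epochs()` so it can be verified against scripted monitor sequences.
* **Monitor**: mean foreground smoothed Dice of argmax predictions
  (evaluation-mode batch-norm), on a capped, deterministic subsample of
  slices (`monitor_max_stacks`) for speed.
* **Class imbalance**: lesion-bearing slices are rare, so mini-batches
  oversample stacks whose centre slice contains foreground
  (`fg_ratio = 0.7` by default). Batches are drawn within one spatial-shape
  group because fine-stage ROI crops differ in extent across cases.
* **Batch normalization**: batch statistics in training, running statistics
  (momentum 0.1) at inference; an `identity` mode exists solely for the
  analytic block tests.
* **Stage decoupling**: the fine stage trains on ground-truth-derived ROI
  crops, not on coarse-stage predictions, so the stages can be trained
  independently and in either order.

# Preprocessing

Intensities are clipped to a configurable HU window (default [−200, 500], a
standard soft-tissue range — CT preprocessing windows vary across
sites, so the window is exposed as configuration rather than asserted as a
fixed truth) and standardized by the mean and standard deviation
of the *normal foreground* — all nonzero-label voxels — pooled over the
training split and frozen (population variance, floored at 1e-6). In-plane
resampling to a fixed extent (512×512 at full scale) uses bilinear
interpolation for intensities and nearest-neighbour for labels. The axial
slice axis is axis 1 of every array, matching the KiTS
`num_slices-height-width` NIfTI layout.

# Evaluation

Per-case smoothed Dice \((2|A\cap B| + 1)/(|A| + |B| + 1)\) is averaged
over cases; two empty masks score 1 by construction of the smoothing.
Hierarchical evaluation classes binarize both volumes by a foreground label
set before scoring — KiTS21: kidney {1,2,3}, mass {2,3}, tumor {2}, cyst
{3}; KiTS19: kidney {1,2}, tumor {2}.

Surface Dice is the fraction of boundary voxels of each mask lying within a
distance tolerance of the other mask's boundary. Boundaries are foreground
voxels with a face-adjacent (6-connectivity) background neighbour, volume
edges counting as background; distances between voxel centres honour
anisotropic spacing via an exact separable Euclidean distance transform.
Conventions stated explicitly because the smoothed Dice and surface
measures disagree on empties: both-empty scores 1, exactly-one-empty scores
0. Published Surface Dice scores rarely state their tolerance, so the
tolerance is a required argument here (2 mm in the examples) rather than a
hidden constant.

# The synthetic world

`generate_case()` builds phantoms with two ellipsoidal kidneys, an optional
spherical-ish tumor and cyst embedded in a kidney (label precedence cyst >
tumor > kidney), class-mean intensities (background −50, kidney 120, tumor
60, cyst 10 HU — chosen for the contrast ordering kidney > tumor > cyst >
background of contrast-enhanced CT, as configuration not anatomy) plus
Gaussian noise (σ = 15 HU by default, typical CT noise magnitude; tests use
10). The default extent 24×96×96 with spacing 3×0.8×0.8 mm keeps CPU
training in minutes while remaining divisible by \(2^{d-1}\) for network
depth ≤ 3 (depth-4/5 nets need larger in-plane extents or the 512×512
resampling path). Cohorts jitter centres, radii and lesion presence
per-case from per-case seeds and record every sampled parameter in a JSON
manifest from which the tree regenerates bit-identically.

What a green test establishes: the plumbing is exact (round trips,
identities), the gradients are correct, and the architecture can learn
smooth high-contrast geometry quickly. What it does not establish: clinical
performance on real CT — real kidneys have texture, partial-volume
boundaries, pathology-distorted anatomy and scanner variation that the
phantoms deliberately omit.

# Numerical and design choices

* 2.5D boundary slices replicate the nearest in-volume slice by default
  (`edge_policy = "zero"` available); boundary handling is a genuine free
  choice in the 2.5D scheme. Replication preserves one-stack-per-slice and avoids
  spurious zero-intensity channels.
* Exactly one prediction per slice — no overlapping-window averaging.
* ROI margins default to 4 slices axially and 16 voxels in-plane; crops are
  grown (within volume bounds) so in-plane extents divide \(2^{d-1}\).
  A single joint box covers both kidneys. When the fine net predicts
  background where the coarse net found kidney, the voxel stays kidney
  (toggleable): the coarse stage owns the organ-level decision.
* Decoder upsampling is bilinear 2× followed by a 1×1 convolution (the
  half-pixel-centre convention with edge clamping); the attention map is
  resampled the same way.
* Weight initialisation is He-normal; the classification head uses a small
  0.01 scale so initial class scores are near-uniform.
* Checkpoints are single `.rds` archives embedding the architecture config;
  run configs are YAML; training history is JSON-lines; every CLI command
  writes a manifest sufficient to reproduce it.
* NIfTI-1 I/O is implemented in the package (gzipped single-file, 3D,
  little/big endian, the common datatypes, sform affine) because no R NIfTI
  reader is available in the target environment; it is validated against a
  Python `nibabel` oracle in the test suite.

# Known limitations

Single-CPU training only; no augmentation; no DICOM; no isotropic
world-space resampling; no per-kidney left/right separation or
connected-component post-processing; published KiTS benchmark numbers are
out of reach without the external datasets and GPU-scale training, and the
package makes no claim about them beyond implementing the method.
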