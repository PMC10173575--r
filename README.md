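# nephroseg

Coarse-to-fine segmentation of kidneys, kidney tumors and cysts in abdominal
CT, implemented as a self-contained R package: a 2.5D slice-stack scheme, a
dual-path attention-gated residual U-shaped network, a two-stage cascade,
KiTS-style evaluation metrics, and a deterministic synthetic phantom
generator so that every component is testable offline. All network forward
*and* backward passes are hand-implemented (hot loops in C++ via
Rcpp/RcppArmadillo) — no external deep-learning runtime is required.

## Who this is for

Medical-image-analysis researchers and engineers who want a transparent,
dependency-light reference implementation of the 2.5D cascade approach used
throughout the KiTS kidney-tumor-segmentation challenge literature: every
layer, gradient and metric is inspectable R/C++ source, and the whole
pipeline runs on a single CPU.

## The method

**2.5D scheme.** A 3D CT volume (shape `num_slices × height × width`, the
KiTS NIfTI convention) is decomposed into stacks of `k` adjacent axial
slices (`k ∈ {3, 5}`, odd). Each stack is the network input; the output is
the segmentation mask of the *middle* slice only. Per-slice masks are then
reassembled into the 3D result, so 2D convolutions see through-plane context
without 3D-convolution memory costs.

**Residual-sum block ("ResConv").** The network's feature block is a 1×1
channel-setting projection followed by two additive residual units whose
outputs are *both* summed into the block output:

    x₀ = Conv₁ₓ₁(input)
    x₁ = ReLU(BN(Conv₃ₓ₃(x₀))) + x₀
    x₂ = ReLU(BN(Conv₃ₓ₃(x₁))) + x₁
    output = x₁ + x₂        (not x₂ alone)

**Dual-path U-Net with attention gates.** The encoder runs two paths: path 1
alternates blocks and 2×2 max pooling; path 2 max-pools the raw input stack
at every level and concatenates it with the pooled features, so deeper
levels keep direct access to low-level intensity information. The decoder
mirrors this with bilinear upsampling and skip connections gated by an
attention mechanism: skip feature `xˡ` and decoder context `g` are projected
to a shared width (A, B), summed (C = A + B), passed through ReLU (D), a 1×1
convolution to one channel (E), a sigmoid (F), and the resampled weight map
α multiplies `xˡ`. The head fuses features from every resolution level.

**Cascade.** Stage 1 segments kidney-vs-background on whole slices; the
margin-expanded bounding box of the kidney mask is cropped; stage 2
classifies tumor (and cyst) inside the crop; labels are pasted back, with
coarse kidney voxels preserved where the fine net is silent.

**Evaluation.** Per-case smoothed Dice, `(2|A∩B| + 1)/(|A| + |B| + 1)`,
averaged over cases and over KiTS hierarchical evaluation classes
(KiTS21: kidney = {1,2,3}, mass = {2,3}, tumor = {2}, cyst = {3};
KiTS19: kidney = {1,2}, tumor = {2}), plus tolerance-based Surface Dice
computed with an exact anisotropic Euclidean distance transform.

## Worked example

```r
library(nephroseg)

# a synthetic KiTS-like case: two ellipsoidal kidneys, a tumor and a cyst
cs <- generate_case(phantom_spec(seed = 7))
cs$volume
#> <ns_volume 'case_00007'  24x96x96  spacing 3x0.8x0.8 mm  range [-116.2, 179.8]>
cs$labels
#> <ns_labels 'case_00007'  24x96x96  KITS21  counts: 0=213007 1=7369 2=603 3=205>

# preprocessing: clip to an HU window, normalize by foreground statistics
stats <- compute_foreground_stats(cs$volume, cs$labels)   # mean 112.9, sd 27.3 HU
vol <- normalize_volume(cs$volume, stats)

# 2.5D stacks: one per axial slice, 3 channels each
stacks <- make_stacks(vol, cs$labels, k = 3)              # 24 stacks, 3x96x96

# the network
net <- net_init(net_config(in_channels = 3, num_classes = 2,
                           depth = 3, base_width = 8), seed = 1)
net
#> <ns_net resconv depth=3 base_width=8 k=3 classes=2 attention=TRUE  (33960 parameters)>

# kidney ROI for the fine stage
extract_roi(cs$labels, margin = c(4, 16, 16))
#> <ns_roi [2,16,2] - [22,83,94] of 24x96x96 (margin 4,16,16)>

# metrics: corrupt two slices of the truth and score all KiTS21 HECs
pred <- cs$labels$labels; pred[9:10, , ] <- 0L
h <- hec_definitions("KITS21")
for (nm in names(h)) {
  a <- array(cs$labels$labels %in% h[[nm]], dim(pred))
  b <- array(pred %in% h[[nm]], dim(pred))
  cat(sprintf("%-6s  Dice %.4f   Surface Dice(2mm) %.4f\n", nm,
              smoothed_dice(a, b), surface_dice(a, b, cs$volume$spacing, 2)))
}
#> kidney  Dice 0.8862   Surface Dice(2mm) 0.8038
#> mass    Dice 0.9404   Surface Dice(2mm) 0.8707
#> tumor   Dice 0.9194   Surface Dice(2mm) 0.8097
#> cyst    Dice 0.9976   Surface Dice(2mm) 0.9967
```

Dropping two axial slices removes a larger share of the kidney than of the
lesions, which is why the kidney class is penalised hardest — the
hierarchical classes respond only to their own foreground sets.

Training and the full cascade are driven the same way (`train_stage()`,
`run_cascade()`, `evaluate_run()`), or from the shell:

```sh
nephroseg make-fixtures --n 20 --seed 1 --out fixtures/
nephroseg train --stage coarse --data fixtures/ --out run/ --epochs 10
nephroseg train --stage fine   --data fixtures/ --out run/ --epochs 10
nephroseg predict --image fixtures/case_00000/imaging.nii.gz \
    --coarse run/coarse.rds --fine run/fine.rds --k 3 --out pred/case_00000
nephroseg evaluate --pred pred/ --labels fixtures/ --vocabulary KITS21 --out report/
```

(the `nephroseg` script is installed under `inst/exec/`; equivalently call
`nephroseg_cli(c("train", "--stage", "coarse", ...))` from R).

## Scope and limitations

Synthetic phantoms are ellipsoids with Gaussian noise: they validate
plumbing, gradients and learnability, not clinical performance. No DICOM
ingestion, no multi-GPU training, no per-kidney splitting or
connected-component post-processing. See the methods vignette
(`vignettes/methods.Rmd`) for the model's assumptions, parameter defaults
and numerical choices.
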