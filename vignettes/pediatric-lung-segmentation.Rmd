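---
title: "Segmenting pediatric chest CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting pediatric chest CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pedlungseg)
```

## The problem

Automatic lung segmentation works well on adult chest CT, but CT of
preschool children is systematically harder for three reasons: children
move, so slices carry streak artifacts; they fail to hold their breath, so
localized parts of the aerated lung disappear into soft-tissue intensities;
and a small child's chest occupies well under 20% of the 512×512
reconstruction circle, so most of the frame is air and table. `pedlungseg`
implements a three-stage pipeline built around exactly these failure modes:

1. **Preprocessing** — Gaussian denoising, then a connected-domain body
   crop that zooms the chest to a uniform working frame, concentrating the
   learning problem on the anatomy.
2. **A 2D ResUnet** — an encoder–decoder whose blocks concatenate their
   input features with their convolved features, trained with a combined
   log-Dice + focal loss.
3. **Case-based filtering** — 3D connected-component analysis of the
   stacked slicewise predictions, keeping the two largest centrally located
   volumes as the left and right lungs.

Because no pediatric CT dataset can ship with the package, a synthetic
phantom generator reproduces the three challenges in controlled form; every
stage of the pipeline is tested end-to-end against it.

## Preprocessing

Each slice is convolved with a normalized, discretely sampled 2D isotropic
Gaussian of width σ = 3 px (separable implementation, mirror padding so
constants are preserved and edges get no dark halo). σ trades noise
suppression against boundary blur; 3 px removes reconstruction noise while
keeping the pleural boundary crisp at 512² resolution.

The body is then located per slice: intensities are clipped to the HU
window (−1000, 400), thresholded at −300 HU (between air and soft tissue),
opened with a disk of radius 3 px (removing thin bridges to blanket or
table), and the largest 2D connected component is taken as the chest. The
circumscribed rectangle of that component — the union across slices, padded
by 8 px and clipped to the frame — defines one crop per case, so the lungs
sit in a stable position across all slices of a case. The crop is zoomed to
256×256 (bilinear for images, nearest-neighbor for masks, which therefore
stay binary), and the `crop_transform` records everything needed to map
predictions back to original coordinates.

The HU window, threshold and opening radius are package choices: the
procedure (threshold → opening → largest connected domain → circumscribed
rectangle → zoom to 256) is fixed, but the numeric values are not dictated
by it, so they were set where CT physics puts them (air ≈ −1000 HU, soft
tissue ≈ 0–60 HU) and are exposed in `preprocess_config()`. Coordinates
are 1-based inclusive (row, col) throughout, the R convention.

## The network

`build_resunet()` assembles a U-shaped encoder–decoder. Its building block
(`res_block()`) passes the input through two (3×3 convolution → batch
normalization → Leaky-ReLU) units and concatenates the unmodified input
with the convolved result along the channel axis — so features of every
scale reach deeper layers unchanged, and the block's output channel count
is the sum of its input and convolved channels. This concatenative form
(rather than additive residuals) is the deliberate reading of the
block's description: the two parts of the concatenation are the output.

Encoder levels apply a block then 2×2 max-pooling; the decoder upsamples
bilinearly, projects channels with a 1×1 convolution, concatenates the
matching encoder output (the U-Net skip), and applies another block. A
final 1×1 convolution and sigmoid produce a per-pixel lung probability.
Dropout (rate 0.2) is applied at the two deepest levels during training.
Leaky-ReLU slope 0.01, batch-norm momentum 0.1 and the binarization
threshold 0.5 are standard defaults, recorded in `model_config()`.

There is no deep-learning framework in the package's dependency set: the
convolutions (im2col + BLAS GEMM in C++), batch-norm, pooling, bilinear
upsampling, their backward passes and the RMSprop optimizer are all
implemented here. Correctness is established by finite-difference tests:
with a linear activation (removing the ReLU kink, which legitimately breaks
finite differences) every parameter gradient of the assembled network
matches central differences to ~1e−6 relative error.

## The loss

Dice loss (`1 − 2|e∩f|/(|e|+|f|)`, implemented with a
`smooth` stabilizer in numerator and denominator) handles the extreme
class imbalance of small lungs in a large frame; focal loss
(`−ɑ(1−y′)^r log y′` on positives, `−(1−ɑ)y′^r log(1−y′)` on negatives,
ɑ = 0.25, r = 2) concentrates on hard boundary pixels. The combined
training objective is

  L_all = α·log(L_Dice) + L_f,  α = 0.3.

Two numeric choices deserve note. First, `log L_Dice` is unbounded below as
the overlap becomes perfect, so the implementation clamps `L_Dice` at
`log_floor = 1e−4` before the logarithm; without the clamp the training
loss diverges to −∞ on easy batches. Second, the logarithm is natural —
the choice only rescales α. The focal-loss ɑ and r are exposed in
`loss_config()` because the block description names them without fixing
them; 0.25 and 2 are the community defaults. Reduction over pixels is the
mean, making the loss batch-size independent.

## Case-based filtering

The model is 2D, so nothing enforces 3D coherence. `case_filter()` stacks
the slicewise predictions, labels 3D connected components (26-connectivity
by default — tolerant of the anisotropic slice spacing of chest protocols;
6-connectivity is available), and keeps at most the two largest components
whose in-plane centroids fall inside the central 80% of the cropped frame.
The crop already centers the thorax, so peripheral blobs are table or
artifact remnants; the location prior makes that explicit. The filter can
only remove voxels — it cannot invent lung where the model predicted none —
and it is idempotent. Degenerate inputs (no component, or none central)
produce an empty mask plus a warning rather than an error.

## Metrics

`confusion()` counts TP/TN/FP/FN voxelwise; `case_metrics()` derives
IOU = TP/(TP+FP+FN), Dice = 2TP/(2TP+FP+FN), precision and recall.
Scores are computed per case over the full 3D volume in **original**
coordinates (after `invert_transform()`), then macro-averaged — every case
counts equally regardless of voxel count, matching per-case reporting
practice. When prediction and reference are both empty all four scores are
defined as 1 (perfect agreement on absence); an empty side against a
nonempty one scores 0. The identity Dice = 2·IOU/(1+IOU) is asserted for
every computed case.

## The phantom generator

`generate_phantom_case()` builds an axial volume from a fixed HU palette
(air −1000, aerated lung −800, soft tissue +40, bone rim +400, table
+300): an elliptical body covering `chest_fraction` (default 0.18) of the
frame, two elliptical lungs whose in-plane size tapers toward apex and
base (so the 3D ground truth always has exactly two components), a bright
table band outside the body, and additive Gaussian noise (default 15 HU).
Streak artifacts are rotated line profiles with a narrow Gaussian
cross-section added to a random subset of slices (default amplitude
150 HU); for a fixed seed the pattern is fixed, so perturbation scales
linearly with amplitude. Breath-hold dropout raises a contiguous
elliptical lung subregion to soft-tissue intensity on randomly selected
slices (default per-slice probability 0.1) and removes it from a
*degraded* working mask while the pristine mask remains the ground truth —
training targets the pristine mask, as a clinician would annotate true
lung extent regardless of transient appearance.

The defaults were chosen once, as plausible desk-scale stand-ins for the
qualitative description of the clinical failure modes; the source data are
not public and the artifacts were never characterized quantitatively, so
no claim of distributional fidelity is made. What passing tests on
phantoms demonstrate is that the pipeline's machinery is correct and that
its stages interact as designed (the crop finds the body, the network
learns the intensity-and-shape rule, the filter removes peripheral false
positives); they do not demonstrate clinical-grade accuracy on real
pediatric CT, where boundaries, pathology and artifact structure are far
richer. Every defect is logged (slice, kind), so tests audit recovery
exactly.

## Training protocol and study sizes

`train_segmentation()` follows the reference protocol: RMSprop (ρ = 0.9)
with initial learning rate 0.001, 10 epochs, combined loss, batch size 8
(a package default; data order is reshuffled each epoch under the run
seed). The test split is case-level — no slice of a held-out case is ever
seen in training — while the train/validation split is image-level with
fraction 0.9, reflecting the reported picture counts. The checkpoint with
the best validation Dice is kept. Divergence (non-finite loss) aborts with
the epoch and batch named.

The packaged end-to-end study runs at reduced scale, chosen once as the
package's benchmark conditions: 24 phantom cases of 16 slices at 256²,
12 held-out test cases, crops zoomed to 128², and a ResUnet with
`base_channels = 8`, `depth = 2` (≈26k parameters). Under these conditions
the pipeline reaches mean Dice ≈ 0.98 on the held-out cases, and the
ablation (plain blocks, no crop, no filter) scores below the full
configuration. The full-scale defaults (512² frames, 256² crops, base 32,
depth 4) are what a GPU-backed run would use; nothing in the code is
specific to the reduced sizes.

## Known limitations

* DICOM series input is not supported (no DICOM reader exists in the
  package's dependency set); use NIfTI or PNG stacks.
* The phantom is geometric, not anatomical: no mediastinal structure,
  airways, gravity-dependent density gradients, or pathology.
* The case filter cannot *add* voxels; recovery of breath-hold dropout
  relies on the trained model bridging degraded slices (which the pristine
  training targets encourage), with the filter guaranteeing only that the
  result is two coherent volumes.
* Training on CPU in R is practical at the benchmark scale; full-scale
  training (tens of thousands of 256² slices) calls for a GPU framework,
  for which the checkpoint format here is not portable.
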