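# pedlungseg

Automatic lung segmentation for chest CT of preschool children (0–6 y).
Pediatric chest CT differs from adult CT in three ways that break
off-the-shelf lung segmenters: motion streak artifacts from patient
shaking, localized loss of aerated-lung appearance when the child cannot
hold their breath, and a chest that occupies less than 20% of the
reconstruction frame. `pedlungseg` implements a three-stage pipeline
designed around those failure modes, for researchers building pediatric
thoracic image-analysis tools:

1. **Preprocessing** — per-slice Gaussian denoising (σ = 3 px), then body
   localization by HU thresholding, morphological opening and largest
   connected domain; the circumscribed rectangle is cropped and zoomed to
   a uniform 256×256 frame (invertibly, via a recorded `crop_transform`).
2. **ResUnet** — a 2D U-shaped encoder–decoder whose blocks concatenate
   input features with convolved features, with Leaky-ReLU, batch
   normalization and dropout, trained by RMSprop (lr 0.001, 10 epochs) on
   the combined loss

   L_all = α·log(L_Dice) + L_f,  α = 0.3,

   where L_Dice(e,f) = 1 − 2|e∩f|/(|e|+|f|) and L_f is the focal loss
   −ɑ(1−y′)^r log y′ / −(1−ɑ)y′^r log(1−y′) (ɑ = 0.25, r = 2). The
   convolution/backprop machinery and the optimizer are implemented in
   the package itself (C++ im2col + BLAS; no deep-learning framework).
3. **Case-based filter** — slicewise predictions are stacked, 3D
   connected components labeled (26-connectivity), and the two largest
   centrally located volumes kept as left and right lungs.

Evaluation reports per-case IOU, Dice, precision and recall
(IOU = TP/(TP+FP+FN), Dice = 2TP/(2TP+FP+FN)) in original coordinates,
macro-averaged over cases.

Because the clinical data this method targets are not publicly
distributable, the package ships a synthetic chest-phantom generator that
reproduces the three challenges with controllable parameters and logged
defects; the entire pipeline is developed and tested against it.

## Worked example

Generate a phantom case, preprocess it, and inspect the crop:

```r
library(pedlungseg)
case <- generate_phantom_case(phantom_spec(n_slices = 6, slice_size = 256,
                                           seed = 3))
case
#> <phantom_case 'phantom-3': 256 x 256 x 6, 7 defects (streak,dropout), seed 3>

pp <- preprocess_case(case$image, case$mask, preprocess_config(out_size = 128))
pp$transform
#> <crop_transform rows 64..185 cols 53..209 of 256x256 -> 128>
```

The full benchmark study — 24 phantom cases, case-level split with 12
held-out test cases, a reduced ResUnet (base 8, depth 2) trained for 10
epochs at 128² — runs in a few minutes on one CPU:

```r
cases <- lapply(1:24, function(i)
  generate_phantom_case(phantom_spec(n_slices = 16, slice_size = 256,
                                     seed = 1000 + i)))
split <- split_dataset(cases, n_test = 12, split = 0.9, seed = 1)
pre   <- preprocess_config(out_size = 128)
data  <- make_training_set(cases, split, pre)
cfg   <- train_config(seed = 1, model = model_config(base_channels = 8,
                                                     depth = 2))
fit   <- train_segmentation(cfg, data, verbose = TRUE)
#> epoch  1  train -0.5852  val 0.9098  val dice 0.4495
#> epoch  2  train -0.9465  val -0.4449  val dice 0.8750
#> ...
#> epoch 10  train -1.2043  val -1.2988  val dice 0.9893

res <- run_pipeline(cases[split$test], fit, pre)
res
#>       case_id    iou   dice precision recall
#>  phantom-1001 0.9656 0.9825    0.9903 0.9749
#>  phantom-1002 0.9692 0.9843    0.9913 0.9775
#>  ...
#>       Average 0.9674 0.9834    0.9909 0.9761
```

Each row scores one held-out case in original coordinates; the Average row
is the unweighted mean. A Dice of 0.98 on phantoms means the machinery
works at this scale — it is not a claim about clinical accuracy on real
pediatric CT (see the methods vignette).

A thin CLI wraps the same functions
(`inst/cli/pedlungseg synth|run-all|evaluate ...`), exchanging volumes as
NIfTI or 16-bit PNG stacks with JSON sidecars.

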