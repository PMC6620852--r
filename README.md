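# myoseg

Instance segmentation of skeletal muscle fibres in H&E-stained histology
images, for quantitative muscle research: fibre cross-section area, size
distributions, and morphology all require every fibre (myofiber) in a
section delineated individually. Muscle cross-sections are hard to segment
because fibres pack tightly into fascicles, separated only by thin, pale,
frequently broken connective-tissue bands — and clinically useful sections
are whole-slide scans, so the method must run on images of essentially
arbitrary size.

## The method

A fully convolutional encoder/multi-decoder network maps an RGB image of
any size to a per-pixel fibre probability map in a single forward pass:

- **Encoder**: VGG-16-style stack (13 conv layers in 5 blocks, fully
  connected layers removed), giving feature maps at strides 1–16.
- **Decoders**: one decoder taps each block just before its max-pool
  (M = 5). Decoder *i* refines its map through *i − 1* steps of
  [learnable 4×4/stride-2 deconvolution → 3×3 conv → ReLU], upsampling
  back to full resolution in small steps. The five one-channel score maps
  are concatenated and merged by a 1×1 convolution (deep supervision:
  every head carries its own loss).
- **Spatially weighted loss**: each head minimizes

  J = −Σᵢ f(Xᵢ) [ 1(Yᵢ=1) log Pᵢ + 1(Yᵢ=0) log(1−Pᵢ) ],
  f(Xᵢ) = C(Yᵢ)⁻¹ · exp(max(ε − Ωᵢ, 0)/η₁) · 1(|Yᵢ − Pᵢ| < η₂)

  with C the label frequency (class balance), Ω the Euclidean distance to
  the nearest fibre contour (boundary errors up-weighted within ε = 10 px),
  and a dynamic switch (η₂ = 0.6) that removes pixels whose annotation the
  network contradicts with high confidence.
- **Two-stage training**: the network first learns to detect fibre
  *boundaries* (an easy pretext close to generic edge features), then is
  fine-tuned on fibre *masks*, preserving the weak-boundary sensitivity
  needed to separate touching fibres. SGD with momentum 0.9, minibatch 2,
  random 300×300 cropping (30 crops/image) as the only augmentation.
- **Evaluation**: per-fibre precision/recall/F1 with maximum-overlap
  matching, reported at the best fixed threshold over the test set (FT)
  and the best threshold per image (DT).
- **Whole-slide inference**: single pass for images up to 2048 px per
  side, overlap-averaged tiling beyond.

Everything — including the convolutions, transposed convolutions and the
full backward pass — is implemented in R/C++ (RcppArmadillo); no deep
learning framework is required. A seeded generator of synthetic
muscle-like images (Lloyd-relaxed Voronoi fibre layouts, H&E-like
rendering, configurable broken boundaries) provides ground-truthed data
for testing and benchmarking.

## Worked example

A desk-scale run — 1/8-width model, 50 synthetic 128 px images — trains in
about five minutes on one CPU core:

```r
library(myoseg)

# 1. Seeded synthetic dataset: 40 training + 10 test images, 128 px
dir <- file.path(tempdir(), "muscle-demo")
make_dataset(50, size_range = c(128, 128), out_dir = dir, seed = 1)
manifest <- read_manifest(file.path(dir, "manifest.tsv"))

# 2. Two-stage fit of a 1/8-width model: boundary pretext, then fibre masks
fit <- myoseg(manifest,
              config    = model_config(width_multiplier = 0.125),
              schedule1 = training_schedule(1, lr = 1e-3, max_iterations = 200),
              schedule2 = training_schedule(2, lr = 1e-3, max_iterations = 400),
              crops_per_image = 30, crop_size = 96,
              switch_warmup = Inf, seed = 2)
print(fit)
#> Two-stage muscle-fibre segmentation fit
#> ...
#> <myoseg_net> 13 encoder conv layers, 5 decoders, 260,387 parameters
#>   stage 1: 200 iterations, final loss/px 1.65710
#>   stage 2: 400 iterations, final loss/px 1.31326

# 3. Held-out evaluation: per-fibre precision/recall/F1 under FT and DT
test  <- manifest[manifest$split == "test", ]
probs <- lapply(test$path_image, function(p) predict(fit, read_image(p)))
gts   <- lapply(test$path_mask,
                function(p) binarize_and_label(read_mask(p) + 0, 0.5, 0))
print(ft_dt_summary(probs, gts))
#> <fiber_eval> FT (t = 0.07): P 0.997±0.001  R 0.982±0.006  F1 0.989±0.003
#>              DT:            P 0.994±0.003  R 0.992±0.003  F1 0.993±0.002

# 4. Label and overlay one test image
img    <- read_image(test$path_image[1])
fibres <- predict(fit, img, type = "labels", threshold = 0.5)
max(fibres)        # 8 fibres recovered
save_overlay(img, fibres, "overlay.png")
```

The `fiber_eval` line reads: at the single fixed threshold that maximizes
mean F1 over the test set (FT), fibre-averaged precision is 0.997 and
recall 0.982; letting each image pick its own best threshold (DT) raises
mean F1 to 0.993. `±` values are standard deviations over the 10 test
images. `switch_warmup = Inf` disables the dynamic switch for this short
run (see the methods vignette for why the gate needs a calibrated network).

The full-size architecture is `model_config()` (width multiplier 1) with
the published schedules `training_schedule(1)` / `training_schedule(2)`;
`load_pretrained_encoder()` initializes the encoder from an external
VGG-16 checkpoint if you have one.

A command-line front end with `synth`, `prepare`, `train`, `predict` and
`evaluate` subcommands is installed under `exec/myoseg`.

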