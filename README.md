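# bsdnet

Bird species detection in camera and video-surveillance imagery, for
ecologists and computer-vision researchers studying wildlife monitoring
pipelines. `bsdnet` is an R implementation of a single-stage convolutional
detector whose two distinctive parts target the field's two structural
difficulties:

* **Dual-branch feature mixer (DBFM).** Bird species share local structure
  (beaks, silhouettes), so the backbone's three downsampling stages fuse a
  local-detail branch (C2F) with a gated global-information branch,

  ```
  F1, F2 = Split(SiLU(BN(Conv1x1(F))))              # 1x1 expands C -> 2C
  GI     = Conv1x1( GELU(DWConv3x3(F1 + F)) * F2 ) + F
  Fd     = SiLU(BN(Conv1x1(Concat(LD, GI))))
  ```

  and downsample by a lossless four-subregion space-to-depth rearrangement
  followed by 1×1 channel mixing, instead of a strided convolution.

* **Prediction balance module (PBM).** Field data are long-tailed. From the
  per-category annotated pixel sums `p_k` the inverse class frequency
  `Pix_k = log(Σ_i p_i / p_k)` scales zero-mean Gaussian noise
  `Variation_k = Pix_k / max_i Pix_i · δ_σ` (default σ = 4) that is added to
  the per-category classification logits during training only — tail
  classes are perturbed most, the head class least — and discarded at
  inference, adding no parameters or FLOPs.

The package also provides COCO detection I/O, letterbox/mosaic/affine
augmentation, the rank-summation detection metrics
(`AP = Σ (R_n − R_{n−1}) P_n`, mAP50/75/50:95), an analytic parameter/FLOP
profiler, an SGD training loop with the reference recipe, and a seeded
generator of synthetic long-tailed multi-object scenes so everything is
testable without downloads. The network engine (im2col convolutions,
reverse-mode tape) is self-contained in R/C++.

## Worked example

Profile the medium-scale detector (200 categories, 640×640), both with the
mixer stages and as the plain Conv+C2F baseline:

```r
library(bsdnet)
profile_models(n_categories = 200, scale = "m", input_size = c(640L, 640L))
#>      model   params params_M   gflops gflops_1dp
#> 1 baseline 25972104     25.9 79.32716       79.3
#> 2  BSD-Net 30647592     30.6 96.34973       96.3
```

The three mixer stages add 4.68 M parameters and 17.0 GFLOPs over the
baseline stages they replace (`params_M` and `gflops_1dp` are truncated to
one decimal, the convention of detector tables). PBM statistics on a toy
three-category set with pixel sums 100 : 10 : 1:

```r
s <- compute_class_pixel_stats(
  data.frame(category = 0:2, w = c(10, 5, 1), h = c(10, 2, 1)), 3)
s$frequency
#> [1] 0.1043600 2.4069451 4.7095302       # log(111/100), log(111/10), log(111)
sd_scale <- 4 * s$frequency / max(s$frequency)  # per-category noise sd at sigma = 4
round(sd_scale, 3)
#> [1] 0.089 2.044 4.000
```

The head category's logits are perturbed with standard deviation 0.09, the
rarest with 4.0. End-to-end on synthetic scenes:

```r
ds  <- generate_dataset(scene_spec(n_categories = 3, n_images = 8,
                                   image_size = c(64L, 64L), seed = 11),
                        "scenes")
mdl <- build_model(bsd_config(3, scale = "custom", width_multiple = 0.125,
                              depth_multiple = 0.33, max_channels = 1024,
                              input_size = c(64L, 64L)))
run <- fit(mdl, ds, train_config(epochs = 200, batch_size = 8,
                                 input_size = c(64L, 64L), augment = FALSE,
                                 pbm = list(enabled = FALSE), seed = 6))
run$history$loss[c(1, 200)]   # training loss falls to ~12% of its start
det <- predict_image(run$model, load_image(ds, 1), conf_threshold = 0.25)
```

A shell entry point wraps the same functions:
`exec/bsdnet profile --classes 200 --scale m --imgsz 640`, plus `synth`,
`train`, `predict`, and `eval` subcommands; every run writes a replayable
manifest.

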