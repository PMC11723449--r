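# Shared fixtures: tiny model configs and a memoized synthetic dataset so
# expensive artifacts are built once per test run.

.fixtures <- new.env(parent = emptyenv())

tiny_cfg <- function(nc = 3L, use_dbfm = TRUE, input = c(64L, 64L)) {
  bsd_config(nc, scale = "custom", use_dbfm = use_dbfm, input_size = input,
             width_multiple = 0.125, depth_multiple = 0.33,
             max_channels = 1024)
}

tiny_model <- function(nc = 3L, use_dbfm = TRUE, input = c(64L, 64L),
                       seed = 42L) {
  set.seed(seed)
  build_model(tiny_cfg(nc, use_dbfm, input))
}

# 8-scene 64x64 dataset with 3 categories, long-tailed
smoke_dataset <- function() {
  if (is.null(.fixtures$smoke_ds)) {
    dir <- file.path(tempdir(), "bsdnet_smoke")
    spec <- scene_spec(n_categories = 3L, n_images = 8L,
                       image_size = c(64L, 64L), imbalance_exponent = 1,
                       objects_per_image = c(1L, 2L),
                       object_scale = c(16L, 32L), motif_overlap = 0.5,
                       seed = 11L)
    .fixtures$smoke_ds <- generate_dataset(spec, dir)
  }
  .fixtures$smoke_ds
}

rand_feat <- function(c, h, w, n = 1L, lim = 1) {
  array(stats::runif(c * h * w * n, -lim, lim), dim = c(h, w, c, n))
}

# Set a conv block's BN to the exact identity transform (the eps offset is
# cancelled so BN contributes nothing to hand-computed oracles).
bn_identity <- function(block) {
  block$bn$running_mean <- rep(0, block$cout)
  block$bn$running_var <- rep(1 - block$bn$eps, block$cout)
  block$bn$gamma$value <- rep(1, block$cout)
  block$bn$beta$value <- rep(0, block$cout)
  invisible(block)
}

fill_weights <- function(p, value) { p$value[] <- value; invisible(p) }
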