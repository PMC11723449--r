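# Detector assembly: stem, three downsampling stages (DBFM or Conv+C2F),
# SPPF, PAFPN neck, decoupled three-scale head; plus analytic parameter and
# FLOP accounting and box decoding/NMS.

REG_MAX <- 16L

round8 <- function(x) max(8L, as.integer(round(x / 8) * 8))

scale_presets <- list(
  n = list(depth = 0.33, width = 0.25, max_channels = 1024),
  s = list(depth = 0.33, width = 0.50, max_channels = 1024),
  m = list(depth = 0.67, width = 0.75, max_channels = 768)
)

#' Model configuration
#'
#' @param n_categories number of object categories (>= 1).
#' @param scale one of `"n"`, `"s"`, `"m"` (medium is the reference
#'   configuration), or `"custom"` with explicit multiples.
#' @param use_dbfm replace the three backbone downsampling stages with
#'   dual-branch feature mixers (`FALSE` gives the plain Conv+C2F baseline).
#' @param input_size `c(h, w)` in pixels, both divisible by 32.
#' @param width_multiple,depth_multiple,max_channels overrides for
#'   `scale = "custom"`.
#' @param pbm list with `enabled`, `sigma`, `seed` controlling the prediction
#'   balance module during training (adds no parameters or FLOPs).
#' @return a config list for [build_model()].
#' @export
bsd_config <- function(n_categories, scale = "m", use_dbfm = TRUE,
                       input_size = c(640L, 640L),
                       width_multiple = NULL, depth_multiple = NULL,
                       max_channels = NULL,
                       pbm = list(enabled = TRUE, sigma = 4, seed = NULL)) {
  if (n_categories < 1L) stop("n_categories must be >= 1")
  if (any(input_size %% 32L != 0L))
    stop("input size must be divisible by 32, got ", paste(input_size, collapse = "x"))
  if (scale != "custom") {
    ps <- scale_presets[[scale]]
    if (is.null(ps)) stop("unknown scale: ", scale)
    width_multiple <- ps$width; depth_multiple <- ps$depth
    max_channels <- ps$max_channels
  }
  pbm <- utils::modifyList(list(enabled = TRUE, sigma = 4, seed = NULL), pbm)
  if (pbm$sigma < 0) stop("pbm.sigma must be >= 0")
  list(n_categories = as.integer(n_categories), scale = scale,
       use_dbfm = isTRUE(use_dbfm), input_size = as.integer(input_size),
       width = width_multiple, depth = depth_multiple,
       max_channels = max_channels, pbm = pbm)
}

# Channel widths of the five backbone levels for a config.
backbone_widths <- function(cfg) {
  base <- c(64, 128, 256, 512, 1024)
  vapply(base, function(c) round8(min(c, cfg$max_channels) * cfg$width), integer(1))
}

scale_depth <- function(n, depth) max(1L, as.integer(round(n * depth)))

# Per-stage DBFM width schedule, relative to the stage input width. The
# fractions were calibrated once so that the medium model meets the module's
# parameter/FLOP budget; they are fixed constants of the architecture.
dbfm_schedule <- function(cin, stage, depth) {
  local_frac <- c(1 / 3, 1 / 2, 4 / 3)[stage]
  fuse_frac <- c(1, 1 / 2, 4)[stage]
  base_rep <- c(2L, 3L, 10L)[stage]
  list(local_width = round8(cin * local_frac),
       fused_width = round8(cin * fuse_frac),
       repeats = scale_depth(base_rep, depth))
}

#' Build the detector
#'
#' Assembles the network described by a [bsd_config()]: a two-convolution
#' stem to stride 4, three downsampling stages (DBFM when `use_dbfm`,
#' otherwise strided Conv + C2F), SPPF on the deepest level, a PAFPN neck
#' with C2F fusion, and a decoupled classification/regression head at
#' strides 8/16/32 with a distribution-focal box representation (16 bins per
#' side).
#'
#' @param cfg a config from [bsd_config()].
#' @return a model object.
#' @export
build_model <- function(cfg) {
  w <- backbone_widths(cfg)
  nd <- function(n) scale_depth(n, cfg$depth)
  nc <- cfg$n_categories
  stage <- function(i) {
    cin <- w[i + 1L]; cout <- w[i + 2L]
    if (cfg$use_dbfm) {
      s <- dbfm_schedule(cin, i, cfg$depth)
      dbfm_block(cin, cout, s$local_width, s$repeats, s$fused_width)
    } else {
      new_block("convc2f", cin = cin, cout = cout,
                modules = list(down = conv_block(cin, cout, 3L, 2L),
                               c2f = c2f_block(cout, cout, nd(if (i == 3L) 3L else 6L), TRUE)))
    }
  }
  chs <- c(w[3], w[4], w[5])
  c2_ <- max(16L, chs[1] %/% 4L, 4L * REG_MAX)
  c3_ <- max(chs[1], min(nc, 100L))
  head_scale <- function(ch) {
    list(box1 = conv_block(ch, c2_, 3L), box2 = conv_block(c2_, c2_, 3L),
         box3 = conv_block(c2_, 4L * REG_MAX, 1L, bn = FALSE, act = "none"),
         cls1 = conv_block(ch, c3_, 3L), cls2 = conv_block(c3_, c3_, 3L),
         cls3 = conv_block(c3_, nc, 1L, bn = FALSE, act = "none"))
  }
  heads <- lapply(chs, head_scale)
  # classification prior: start near p = 0.01 so early training is stable
  for (h in heads) h$cls3$params$b$value <- rep(log(0.01 / 0.99), nc)
  model <- list(
    cfg = cfg,
    strides = c(8L, 16L, 32L),
    backbone = list(
      stem1 = conv_block(3L, w[1], 3L, 2L),
      stem2 = conv_block(w[1], w[2], 3L, 2L),
      c2f_p2 = c2f_block(w[2], w[2], nd(3L), TRUE),
      stage3 = stage(1L), stage4 = stage(2L), stage5 = stage(3L),
      sppf = sppf_block(w[5], w[5])),
    neck = list(
      td1 = c2f_block(w[5] + w[4], w[4], nd(3L), FALSE),
      td2 = c2f_block(w[4] + w[3], w[3], nd(3L), FALSE),
      bu1 = conv_block(w[3], w[3], 3L, 2L),
      bu2 = c2f_block(w[3] + w[4], w[4], nd(3L), FALSE),
      bu3 = conv_block(w[4], w[4], 3L, 2L),
      bu4 = c2f_block(w[4] + w[5], w[5], nd(3L), FALSE)),
    head = heads)
  class(model) <- "bsd_model"
  model
}

fwd.bsd_convc2f <- function(m, x, training = FALSE) {
  fwd(m$modules$c2f, fwd(m$modules$down, x, training), training)
}

block_flops.bsd_convc2f <- function(m, h, w) {
  f1 <- block_flops(m$modules$down, h, w)
  f2 <- block_flops(m$modules$c2f, f1$h, f1$w)
  list(flops = f1$flops + f2$flops, h = f1$h, w = f1$w)
}

#' Forward pass
#'
#' @param model a built model.
#' @param x image batch array (H, W, 3, N), H and W divisible by 32.
#' @param training training mode (batch-stat BN, gradient tape if active).
#' @return list of three arrays (H/s, W/s, 64 + n_categories, N) at strides
#'   8, 16, 32; the first 64 channels are the distribution-focal box logits
#'   (4 sides x 16 bins), the rest per-category classification logits.
#' @export
model_forward <- function(model, x, training = FALSE) {
  d <- dim(vof(x))
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("input spatial size must be divisible by 32, got ", d[1], "x", d[2])
  b <- model$backbone
  p2 <- fwd(b$c2f_p2, fwd(b$stem2, fwd(b$stem1, x, training), training), training)
  p3 <- fwd(b$stage3, p2, training)
  p4 <- fwd(b$stage4, p3, training)
  p5 <- fwd(b$sppf, fwd(b$stage5, p4, training), training)
  n <- model$neck
  t4 <- fwd(n$td1, op_concat(list(op_upsample2(p5), p4)), training)
  t3 <- fwd(n$td2, op_concat(list(op_upsample2(t4), p3)), training)
  u4 <- fwd(n$bu2, op_concat(list(fwd(n$bu1, t3, training), t4)), training)
  u5 <- fwd(n$bu4, op_concat(list(fwd(n$bu3, u4, training), p5)), training)
  feats <- list(t3, u4, u5)
  lapply(seq_len(3L), function(i) {
    h <- model$head[[i]]; f <- feats[[i]]
    box <- fwd(h$box3, fwd(h$box2, fwd(h$box1, f, training), training), training)
    cls <- fwd(h$cls3, fwd(h$cls2, fwd(h$cls1, f, training), training), training)
    op_concat(list(box, cls))
  })
}

#' Count trainable parameters
#'
#' Sums the lengths of all trainable arrays (convolution weights and biases,
#' batch-norm scale and shift). Running BN statistics and the fixed
#' distribution-focal projection are not trainable and are excluded.
#'
#' @param model a built model.
#' @return integer scalar.
#' @export
count_parameters <- function(model) {
  n_params(list(model$backbone, model$neck, model$head))
}

#' Count forward FLOPs
#'
#' Analytic count over convolutions and linear maps at the given input size,
#' batch 1, with one multiply-accumulate = 2 FLOPs. Pooling, activations,
#' upsampling and the space-to-depth rearrangement are free by convention
#' (they carry no multiplies).
#'
#' @param model a built model.
#' @param input_size `c(h, w)`; defaults to the model's configured size.
#' @return FLOPs (a plain double; divide by 1e9 for GFLOPs).
#' @export
count_flops <- function(model, input_size = NULL) {
  if (is.null(input_size)) input_size <- model$cfg$input_size
  h <- input_size[1]; w <- input_size[2]
  total <- 0
  b <- model$backbone
  step <- function(m, h, w) {
    r <- block_flops(m, h, w)
    total <<- total + r$flops
    c(r$h, r$w)
  }
  s <- step(b$stem1, h, w); s <- step(b$stem2, s[1], s[2])
  s <- step(b$c2f_p2, s[1], s[2])
  p3 <- step(b$stage3, s[1], s[2])
  p4 <- step(b$stage4, p3[1], p3[2])
  p5 <- step(b$stage5, p4[1], p4[2])
  p5 <- step(b$sppf, p5[1], p5[2])
  n <- model$neck
  step(n$td1, p4[1], p4[2])
  step(n$td2, p3[1], p3[2])
  step(n$bu1, p3[1], p3[2])
  step(n$bu2, p4[1], p4[2])
  step(n$bu3, p4[1], p4[2])
  step(n$bu4, p5[1], p5[2])
  hw <- list(p3, p4, p5)
  for (i in 1:3) {
    for (mm in model$head[[i]]) step(mm, hw[[i]][1], hw[[i]][2])
  }
  total
}

#' Parameter/FLOP profile of baseline and DBFM variants
#'
#' @param n_categories,scale,input_size as in [bsd_config()].
#' @return data.frame with one row per variant; params in M and GFLOPs are
#'   truncated (not rounded) to one decimal, the convention of the YOLO
#'   family's published tables.
#' @export
profile_models <- function(n_categories = 200L, scale = "m",
                           input_size = c(640L, 640L)) {
  row <- function(use_dbfm) {
    m <- build_model(bsd_config(n_categories, scale, use_dbfm, input_size))
    p <- count_parameters(m)
    f <- count_flops(m)
    data.frame(model = if (use_dbfm) "BSD-Net" else "baseline",
               params = p, params_M = trunc1(p / 1e6),
               gflops = f / 1e9, gflops_1dp = trunc1(f / 1e9))
  }
  rbind(row(FALSE), row(TRUE))
}

# one-decimal truncation (37.97 -> 37.9), as printed in detector tables
trunc1 <- function(x) floor(x * 10 + 1e-9) / 10

# --- decoding and NMS -------------------------------------------------------

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# Decode one scale's raw grid (H, W, 64+nc) to boxes in network-input pixels.
decode_grid <- function(grid, stride, nc, conf_threshold) {
  d <- dim(grid)
  H <- d[1]; W <- d[2]
  ncell <- H * W
  box <- matrix(grid[, , 1:(4 * REG_MAX), 1], nrow = ncell)
  cls <- matrix(grid[, , 4 * REG_MAX + seq_len(nc), 1], nrow = ncell)
  prob <- 1 / (1 + exp(-cls))
  conf <- apply(prob, 1, max)
  keep <- which(conf >= conf_threshold)
  if (length(keep) == 0L)
    return(data.frame(category = integer(0), confidence = numeric(0),
                      x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0)))
  cat_idx <- max.col(prob[keep, , drop = FALSE], ties.method = "first")
  dists <- sapply(1:4, function(s) {
    z <- box[keep, (s - 1) * REG_MAX + seq_len(REG_MAX), drop = FALSE]
    p <- softmax_rows(z)
    as.vector(p %*% (seq_len(REG_MAX) - 1))
  })
  if (length(keep) == 1L) dists <- matrix(dists, nrow = 1)
  gy <- (keep - 1) %% H          # 0-based row
  gx <- (keep - 1) %/% H         # 0-based col
  cx <- (gx + 0.5) * stride; cy <- (gy + 0.5) * stride
  data.frame(category = cat_idx - 1L, confidence = conf[keep],
             x1 = cx - dists[, 1] * stride, y1 = cy - dists[, 2] * stride,
             x2 = cx + dists[, 3] * stride, y2 = cy + dists[, 4] * stride)
}

# Greedy per-category non-maximum suppression; input must be sorted by
# descending confidence. Returns the kept row indices, order preserved.
nms_keep <- function(det, iou_nms) {
  n <- nrow(det)
  if (n == 0L) return(integer(0))
  keep <- logical(n)
  for (cat in unique(det$category)) {
    idx <- which(det$category == cat)
    taken <- integer(0)
    for (i in idx) {
      if (length(taken) == 0L) { keep[i] <- TRUE; taken <- i; next }
      ious <- vapply(taken, function(j)
        box_iou(as.numeric(det[i, c("x1", "y1", "x2", "y2")]),
                as.numeric(det[j, c("x1", "y1", "x2", "y2")])), numeric(1))
      if (all(ious <= iou_nms)) { keep[i] <- TRUE; taken <- c(taken, i) }
    }
  }
  which(keep)
}

#' Run detection on a single image
#'
#' Letterboxes the image to the model's input size, runs the network in
#' inference mode, decodes the distribution-focal boxes, maps them back to
#' original image coordinates, clips to bounds and applies per-category NMS.
#'
#' @param model a built model.
#' @param image array (H, W, 3) with values in `[0, 1]`.
#' @param conf_threshold minimum classification confidence in (0, 1).
#' @param iou_nms IoU above which a lower-scoring same-category box is
#'   suppressed.
#' @return data.frame (category, confidence, x1, y1, x2, y2), sorted by
#'   descending confidence; 0-based half-open pixel boxes.
#' @export
predict_image <- function(model, image, conf_threshold = 0.25, iou_nms = 0.7) {
  if (conf_threshold <= 0 || conf_threshold > 1) stop("conf_threshold in (0, 1]")
  lb <- letterbox(image, NULL, model$cfg$input_size)
  x <- array(lb$image, dim = c(dim(lb$image)[1:2], 3L, 1L))
  preds <- model_forward(model, x, training = FALSE)
  nc <- model$cfg$n_categories
  det <- do.call(rbind, lapply(seq_len(3L), function(i)
    decode_grid(vof(preds[[i]]), model$strides[i], nc, conf_threshold)))
  if (nrow(det) > 0) {
    # undo letterbox
    det$x1 <- (det$x1 - lb$pad[2]) / lb$scale[2]
    det$x2 <- (det$x2 - lb$pad[2]) / lb$scale[2]
    det$y1 <- (det$y1 - lb$pad[1]) / lb$scale[1]
    det$y2 <- (det$y2 - lb$pad[1]) / lb$scale[1]
    h <- dim(image)[1]; w <- dim(image)[2]
    det$x1 <- pmin(pmax(det$x1, 0), w); det$x2 <- pmin(pmax(det$x2, 0), w)
    det$y1 <- pmin(pmax(det$y1, 0), h); det$y2 <- pmin(pmax(det$y2, 0), h)
    det <- det[det$x2 > det$x1 & det$y2 > det$y1, , drop = FALSE]
    ord <- order(-det$confidence, det$category, det$x1, det$y1)
    det <- det[ord, , drop = FALSE]
    det <- det[nms_keep(det, iou_nms), , drop = FALSE]
    rownames(det) <- NULL
  }
  det
}

# --- checkpoints ------------------------------------------------------------

model_state <- function(model) {
  params <- collect_params(list(model$backbone, model$neck, model$head))
  bns <- collect_bns(list(model$backbone, model$neck, model$head))
  list(params = lapply(params, function(p) p$value),
       running = lapply(bns, function(b) list(mean = b$running_mean,
                                              var = b$running_var)))
}

collect_bns <- function(m) {
  out <- list()
  if (inherits(m, "bsd_block")) {
    if (!is.null(m$bn)) out <- c(out, list(m$bn))
    for (child in m$modules) out <- c(out, collect_bns(child))
  } else if (is.list(m)) {
    for (child in m) out <- c(out, collect_bns(child))
  }
  out
}

restore_state <- function(model, state) {
  params <- collect_params(list(model$backbone, model$neck, model$head))
  stopifnot(length(params) == length(state$params))
  for (i in seq_along(params)) params[[i]]$value <- state$params[[i]]
  bns <- collect_bns(list(model$backbone, model$neck, model$head))
  stopifnot(length(bns) == length(state$running))
  for (i in seq_along(bns)) {
    bns[[i]]$running_mean <- state$running[[i]]$mean
    bns[[i]]$running_var <- state$running[[i]]$var
  }
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the config, so [load_checkpoint()] rebuilds the
#' architecture and restores the weights and BN statistics.
#'
#' @param model a built model.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(cfg = model$cfg, state = model_state(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg)
  restore_state(model, ck$state)
}
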