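# Training: center-based target assignment across the three scales, the
# composite detection loss (BCE classification with PBM logit perturbation,
# CIoU + distribution-focal box regression), and an SGD loop with warmup,
# cosine decay, mosaic scheduling and seeded reproducibility.
#
# The loss internals are differentiated in closed form (softmax-expectation
# chain for the focal bins, piecewise-linear CIoU geometry) and injected
# into the tape as a single scalar node.

# call counters used by tests to assert schedule/inference-purity contracts
.counters <- new.env(parent = emptyenv())

counter_bump <- function(name) {
  .counters[[name]] <- (.counters[[name]] %||% 0L) + 1L
  invisible(NULL)
}

#' Read or reset internal call counters (instrumentation)
#' @param name counter name, e.g. `"mosaic"` or `"sample_variation"`.
#' @export
bsd_counter <- function(name) .counters[[name]] %||% 0L

#' @rdname bsd_counter
#' @export
bsd_counter_reset <- function(name) { .counters[[name]] <- 0L; invisible(NULL) }

#' Training configuration
#'
#' Defaults follow the reference recipe: 100 epochs from scratch, batch 16,
#' SGD with initial learning rate 0.01 and momentum 0.937, mosaic
#' augmentation disabled for the last ten epochs.
#'
#' @param epochs,batch_size,lr0,momentum,weight_decay optimizer settings.
#' @param warmup_epochs linear warmup length; cosine decay to `lrf * lr0`
#'   afterwards.
#' @param lrf final learning-rate fraction.
#' @param mosaic_off_last disable mosaic for this many final epochs.
#' @param augment apply mosaic + random zoom/translation.
#' @param input_size network input `c(h, w)`.
#' @param pbm list(enabled, sigma) for the prediction balance module.
#' @param seed master seed governing shuffling, augmentation, PBM draws.
#' @param val_interval run validation mAP every this many epochs (0 = only
#'   at the end).
#' @export
train_config <- function(epochs = 100L, batch_size = 16L, lr0 = 0.01,
                         momentum = 0.937, weight_decay = 5e-4,
                         warmup_epochs = 3L, lrf = 0.01,
                         mosaic_off_last = 10L, augment = TRUE,
                         input_size = c(640L, 640L),
                         pbm = list(enabled = TRUE, sigma = 4),
                         seed = 0L, val_interval = 0L) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (mosaic_off_last > epochs) stop("mosaic_off_last must be <= epochs")
  pbm <- utils::modifyList(list(enabled = TRUE, sigma = 4), pbm)
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr0 = lr0, momentum = momentum, weight_decay = weight_decay,
       warmup_epochs = warmup_epochs, lrf = lrf,
       mosaic_off_last = as.integer(mosaic_off_last), augment = isTRUE(augment),
       input_size = as.integer(input_size), pbm = pbm,
       seed = as.integer(seed), val_interval = as.integer(val_interval))
}

#' Assign ground-truth boxes to prediction cells
#'
#' Each ground truth goes to the scale whose stride best matches its size
#' (largest side about four cells) and to the cell containing its center;
#' all other cells are background and carry no box loss. When two GT compete
#' for a cell the larger box wins (ties: lower category, then coordinates)
#' and the loser falls back to the nearest free 4-neighbor cell, so every GT
#' keeps at least one positive cell except in pathologically crowded
#' neighborhoods. The precedence makes assignment invariant to GT ordering.
#'
#' @param gt data.frame (category, x1, y1, x2, y2) in network-input pixels.
#' @param input_size `c(h, w)`.
#' @param strides stride ladder, default `c(8, 16, 32)`.
#' @return list per scale: data.frame (gy, gx 0-based cell, category,
#'   l, t, r, b target distances in stride units, plus the GT box in stride
#'   units gx1..gy2).
#' @export
assign_targets <- function(gt, input_size, strides = c(8L, 16L, 32L)) {
  out <- lapply(strides, function(s)
    data.frame(gy = integer(0), gx = integer(0), category = integer(0),
               l = numeric(0), t = numeric(0), r = numeric(0), b = numeric(0),
               gx1 = numeric(0), gy1 = numeric(0), gx2 = numeric(0),
               gy2 = numeric(0)))
  if (is.null(gt) || nrow(gt) == 0L) return(out)
  side <- pmax(gt$x2 - gt$x1, gt$y2 - gt$y1)
  sc <- vapply(side, function(m)
    which.min(abs(log2(pmax(m, 1) / (4 * strides)))), integer(1))
  # deterministic precedence: larger area first, then category, then coords
  area <- (gt$x2 - gt$x1) * (gt$y2 - gt$y1)
  ord <- order(-area, gt$category, gt$x1, gt$y1, gt$x2, gt$y2)
  for (i in ord) {
    s <- strides[sc[i]]
    H <- input_size[1] %/% s; W <- input_size[2] %/% s
    cx <- (gt$x1[i] + gt$x2[i]) / 2 / s
    cy <- (gt$y1[i] + gt$y2[i]) / 2 / s
    gx <- min(max(floor(cx), 0), W - 1); gy <- min(max(floor(cy), 0), H - 1)
    tbl <- out[[sc[i]]]
    # center cell first; if a larger box holds it, fall back to the free
    # 4-neighbor nearest the box center (deterministic order)
    cand <- rbind(c(gy, gx), c(gy, gx - 1), c(gy, gx + 1),
                  c(gy - 1, gx), c(gy + 1, gx))
    cand <- cand[cand[, 1] >= 0 & cand[, 1] < H &
                   cand[, 2] >= 0 & cand[, 2] < W, , drop = FALSE]
    free <- !apply(cand, 1, function(cc) any(tbl$gy == cc[1] & tbl$gx == cc[2]))
    if (!any(free)) next
    gy <- cand[which(free)[1], 1]; gx <- cand[which(free)[1], 2]
    d <- c(l = (gx + 0.5) - gt$x1[i] / s, t = (gy + 0.5) - gt$y1[i] / s,
           r = gt$x2[i] / s - (gx + 0.5), b = gt$y2[i] / s - (gy + 0.5))
    d <- pmin(pmax(d, 0), REG_MAX - 1 - 0.01)
    out[[sc[i]]] <- rbind(tbl, data.frame(
      gy = gy, gx = gx, category = gt$category[i],
      l = d[["l"]], t = d[["t"]], r = d[["r"]], b = d[["b"]],
      gx1 = gt$x1[i] / s, gy1 = gt$y1[i] / s,
      gx2 = gt$x2[i] / s, gy2 = gt$y2[i] / s))
  }
  out
}

# Complete-IoU between a predicted box and a GT box (both x1 y1 x2 y2 in the
# same units); returns the value and the gradient w.r.t. the predicted box.
# The aspect-ratio weight alpha is treated as a constant, the usual CIoU
# convention.
ciou_with_grad <- function(p, g) {
  eps <- 1e-9
  w1 <- p[3] - p[1]; h1 <- p[4] - p[2]
  w2 <- g[3] - g[1]; h2 <- g[4] - g[2]
  xi1 <- max(p[1], g[1]); yi1 <- max(p[2], g[2])
  xi2 <- min(p[3], g[3]); yi2 <- min(p[4], g[4])
  iw <- xi2 - xi1; ih <- yi2 - yi1
  I <- if (iw > 0 && ih > 0) iw * ih else 0
  U <- w1 * h1 + w2 * h2 - I + eps
  iou <- I / U
  dI <- rep(0, 4)
  if (I > 0) {
    dI[1] <- -ih * (p[1] > g[1]); dI[3] <- ih * (p[3] < g[3])
    dI[2] <- -iw * (p[2] > g[2]); dI[4] <- iw * (p[4] < g[4])
  }
  dU <- c(-h1 - dI[1], -w1 - dI[2], h1 - dI[3], w1 - dI[4])
  diou <- (dI * U - I * dU) / U^2
  # center distance over enclosing diagonal
  xc1 <- min(p[1], g[1]); yc1 <- min(p[2], g[2])
  xc2 <- max(p[3], g[3]); yc2 <- max(p[4], g[4])
  cw <- xc2 - xc1; chh <- yc2 - yc1
  c2 <- cw^2 + chh^2 + eps
  bcx <- (p[1] + p[3]) / 2; bcy <- (p[2] + p[4]) / 2
  gcx <- (g[1] + g[3]) / 2; gcy <- (g[2] + g[4]) / 2
  rho2 <- (bcx - gcx)^2 + (bcy - gcy)^2
  drho2 <- c(bcx - gcx, bcy - gcy, bcx - gcx, bcy - gcy)
  dcw <- c(-(p[1] < g[1]), 0, (p[3] > g[3]), 0)
  dch <- c(0, -(p[2] < g[2]), 0, (p[4] > g[4]))
  dc2 <- 2 * cw * dcw + 2 * chh * dch
  dpen <- (drho2 * c2 - rho2 * dc2) / c2^2
  # aspect term
  t1 <- atan(w1 / (h1 + eps)); t2 <- atan(w2 / (h2 + eps))
  k <- 4 / pi^2
  v <- k * (t2 - t1)^2
  alpha <- v / (1 - iou + v + eps)
  # t1 = atan(w1/h1): dt1/dw1 = h1/den, dt1/dh1 = -w1/den; w1/h1 depend on
  # (x1,y1,x2,y2) as (-1,-1,+1,+1) on (w1 via x, h1 via y)
  den <- w1^2 + h1^2 + eps
  dt1 <- c(-h1 / den, w1 / den, h1 / den, -w1 / den)
  dv <- -2 * k * (t2 - t1) * dt1
  val <- iou - rho2 / c2 - alpha * v
  grad <- diou - dpen - alpha * dv
  list(ciou = val, grad = grad, alpha = alpha)
}

#' Detection loss with closed-form gradients
#'
#' Components: binary cross-entropy over all cells' per-category logits
#' (perturbed by the PBM variation vector when `training`), CIoU box loss
#' and distribution-focal loss at positive cells. Weights follow the YOLO
#' convention 7.5 (box) / 0.5 (cls) / 1.5 (dfl).
#'
#' @param preds list of three prediction grids from [model_forward()]
#'   (nodes or arrays).
#' @param assignments per-image list of [assign_targets()] results (one
#'   entry per batch element).
#' @param n_categories C.
#' @param variation PBM variation vector (length C) or NULL.
#' @param training training mode flag; out of training the perturbation is
#'   never applied.
#' @return list: `loss` (scalar node when a tape is active, else numeric),
#'   `box`, `cls`, `dfl` components, `n_pos`.
#' @export
compute_loss <- function(preds, assignments, n_categories,
                         variation = NULL, training = TRUE) {
  nc <- n_categories
  w_box <- 7.5; w_cls <- 0.5; w_dfl <- 1.5
  n_pos <- sum(vapply(assignments, function(a)
    sum(vapply(a, nrow, integer(1))), numeric(1)))
  norm <- max(n_pos, 1)
  loss_box <- 0; loss_cls <- 0; loss_dfl <- 0
  pairs <- list()
  for (si in seq_along(preds)) {
    pv <- vof(preds[[si]])
    if (any(!is.finite(pv)))
      stop("non-finite values in scale-", si, " predictions")
    d <- dim(pv)
    H <- d[1]; W <- d[2]; N <- d[4]
    g <- array(0, dim = d)
    # classification: BCE over every cell
    z <- pv[, , 4 * REG_MAX + seq_len(nc), , drop = FALSE]
    if (training && !is.null(variation) && any(variation != 0))
      z <- z + rep(rep(as.numeric(variation), each = H * W), times = N)
    tgt <- array(0, dim = dim(z))
    for (n in seq_len(N)) {
      a <- assignments[[n]][[si]]
      if (nrow(a) > 0)
        tgt[cbind(a$gy + 1L, a$gx + 1L, a$category + 1L, n)] <- 1
    }
    p <- 1 / (1 + exp(-z))
    bce <- -(tgt * log(pmax(p, 1e-12)) + (1 - tgt) * log(pmax(1 - p, 1e-12)))
    loss_cls <- loss_cls + sum(bce) / norm
    g[, , 4 * REG_MAX + seq_len(nc), ] <- (p - tgt) / norm * w_cls
    # box + dfl at positive cells
    for (n in seq_len(N)) {
      a <- assignments[[n]][[si]]
      if (nrow(a) == 0L) next
      for (ri in seq_len(nrow(a))) {
        gy <- a$gy[ri] + 1L; gx <- a$gx[ri] + 1L
        zbox <- matrix(pv[gy, gx, 1:(4 * REG_MAX), n], nrow = 4, byrow = TRUE)
        prob <- exp(zbox - apply(zbox, 1, max))
        prob <- prob / rowSums(prob)
        bins <- seq_len(REG_MAX) - 1
        dist <- as.numeric(prob %*% bins)           # (l, t, r, b)
        cx <- a$gx[ri] + 0.5; cy <- a$gy[ri] + 0.5
        pbox <- c(cx - dist[1], cy - dist[2], cx + dist[3], cy + dist[4])
        gbox <- c(a$gx1[ri], a$gy1[ri], a$gx2[ri], a$gy2[ri])
        ci <- ciou_with_grad(pbox, gbox)
        loss_box <- loss_box + (1 - ci$ciou) / norm
        dbox_ddist <- c(-ci$grad[1], -ci$grad[2], ci$grad[3], ci$grad[4])
        td <- c(a$l[ri], a$t[ri], a$r[ri], a$b[ri])
        gz <- matrix(0, 4, REG_MAX)
        for (s4 in 1:4) {
          # CIoU chain through the softmax expectation
          gz[s4, ] <- gz[s4, ] + (-dbox_ddist[s4] / norm * w_box) *
            prob[s4, ] * (bins - dist[s4])
          # distribution-focal cross-entropy to the two adjacent bins
          li <- floor(td[s4]); wr <- td[s4] - li
          tdist <- rep(0, REG_MAX)
          tdist[li + 1L] <- 1 - wr
          if (li + 2L <= REG_MAX) tdist[li + 2L] <- wr
          loss_dfl <- loss_dfl - sum(tdist * log(pmax(prob[s4, ], 1e-12))) / (4 * norm)
          gz[s4, ] <- gz[s4, ] + (prob[s4, ] - tdist) / (4 * norm) * w_dfl
        }
        g[gy, gx, 1:(4 * REG_MAX), n] <-
          g[gy, gx, 1:(4 * REG_MAX), n] + as.numeric(t(gz))
      }
    }
    pairs[[si]] <- list(node = preds[[si]], grad = g)
  }
  total <- w_box * loss_box + w_cls * loss_cls + w_dfl * loss_dfl
  list(loss = op_inject(total, pairs), box = loss_box, cls = loss_cls,
       dfl = loss_dfl, n_pos = n_pos)
}

# --- optimizer --------------------------------------------------------------

sgd_state <- function(params) lapply(params, function(p) 0)

sgd_step <- function(params, state, lr, momentum, weight_decay) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad
    # decay conv weights only (rank-4 arrays), the YOLO convention
    if (weight_decay > 0 && length(dim(p$value)) == 4L)
      g <- g + weight_decay * p$value
    state[[i]] <- momentum * state[[i]] - lr * g
    p$value <- p$value + state[[i]]
  }
  state
}

lr_at <- function(epoch, cfg) {
  if (epoch <= cfg$warmup_epochs && cfg$warmup_epochs > 0)
    return(cfg$lr0 * epoch / cfg$warmup_epochs)
  t <- (epoch - cfg$warmup_epochs) / max(cfg$epochs - cfg$warmup_epochs, 1)
  cfg$lr0 * (cfg$lrf + (1 - cfg$lrf) * (1 + cos(pi * t)) / 2)
}

# Assemble one batch: returns x (H, W, 3, N) and per-image GT in input px.
make_batch <- function(dataset, ids, cache, cfg, use_mosaic) {
  N <- length(ids)
  x <- array(0, dim = c(cfg$input_size[1], cfg$input_size[2], 3L, N))
  gts <- vector("list", N)
  all_ids <- dataset$images$id
  for (k in seq_len(N)) {
    id <- ids[k]
    img <- cache[[as.character(id)]]
    bx <- dataset$annotations[dataset$annotations$image_id == id, , drop = FALSE]
    if (use_mosaic) {
      counter_bump("mosaic")
      others <- sample(all_ids, 3L, replace = length(all_ids) < 4L)
      imgs <- c(list(img), lapply(others, function(o) cache[[as.character(o)]]))
      bxs <- c(list(bx), lapply(others, function(o)
        dataset$annotations[dataset$annotations$image_id == o, , drop = FALSE]))
      mz <- mosaic_augment(imgs, bxs)
      img <- mz$image; bx <- mz$boxes %||% bx[0, ]
    }
    if (cfg$augment) {
      af <- random_affine(img, bx)
      img <- af$image; bx <- af$boxes %||% bx[0, ]
    }
    lb <- letterbox(img, bx, cfg$input_size)
    x[, , , k] <- lb$image
    bx <- lb$boxes %||% bx[0, ]
    gts[[k]] <- clip_boxes(bx, cfg$input_size[1], cfg$input_size[2])
  }
  list(x = x, gts = gts)
}

#' Train a detector
#'
#' Runs the SGD recipe over a dataset: seeded shuffling, optional mosaic +
#' zoom/translation augmentation (mosaic disabled for the final
#' `mosaic_off_last` epochs), PBM logit perturbation resampled once per
#' batch, per-epoch loss history, optional validation mAP and
#' best-checkpoint tracking. Aborts on divergence, returning the last
#' finite-state model.
#'
#' @param model a built model.
#' @param dataset a `bsd_dataset` with images on disk.
#' @param cfg a [train_config()].
#' @param val_dataset optional validation `bsd_dataset`.
#' @return list: `model`, `history` (data.frame epoch, loss, box, cls, dfl,
#'   lr, mAP50), `best_mAP50`.
#' @export
fit <- function(model, dataset, cfg = train_config(), val_dataset = NULL) {
  if (nrow(dataset$images) == 0L) stop("empty dataset")
  set.seed(cfg$seed)
  nc <- model$cfg$n_categories
  params <- collect_params(list(model$backbone, model$neck, model$head))
  opt <- sgd_state(params)
  cache <- new.env(parent = emptyenv())
  for (id in dataset$images$id)
    cache[[as.character(id)]] <- load_image(dataset, id)
  stats <- compute_class_pixel_stats(
    data.frame(category = dataset$annotations$category,
               w = dataset$annotations$x2 - dataset$annotations$x1,
               h = dataset$annotations$y2 - dataset$annotations$y1), nc)
  history <- NULL
  best <- list(mAP50 = -Inf, state = NULL)
  last_good <- model_state(model)
  for (epoch in seq_len(cfg$epochs)) {
    use_mosaic <- cfg$augment && epoch <= cfg$epochs - cfg$mosaic_off_last
    ids <- sample(dataset$images$id)
    lr <- lr_at(epoch, cfg)
    ep <- c(loss = 0, box = 0, cls = 0, dfl = 0)
    nb <- 0L
    for (start in seq(1L, length(ids), by = cfg$batch_size)) {
      bids <- ids[start:min(start + cfg$batch_size - 1L, length(ids))]
      batch <- make_batch(dataset, bids, cache, cfg, use_mosaic)
      variation <- if (isTRUE(cfg$pbm$enabled))
        sample_variation_internal(stats, cfg$pbm$sigma) else NULL
      zero_grads(params)
      ag_start()
      preds <- model_forward(model, batch$x, training = TRUE)
      assignments <- lapply(batch$gts, assign_targets,
                            input_size = cfg$input_size,
                            strides = model$strides)
      l <- compute_loss(preds, assignments, nc, variation, training = TRUE)
      if (!is.finite(vof(l$loss))) {
        ag_stop()
        warning("divergence at epoch ", epoch, "; restoring last checkpoint")
        restore_state(model, last_good)
        return(list(model = model, history = history,
                    best_mAP50 = best$mAP50, diverged = TRUE))
      }
      ag_backward(l$loss)
      ag_stop()
      opt <- sgd_step(params, opt, lr, cfg$momentum, cfg$weight_decay)
      ep <- ep + c(vof(l$loss), l$box, l$cls, l$dfl)
      nb <- nb + 1L
    }
    last_good <- model_state(model)
    ep <- ep / nb
    m50 <- NA_real_
    validate <- !is.null(val_dataset) &&
      (epoch == cfg$epochs ||
         (cfg$val_interval > 0 && epoch %% cfg$val_interval == 0L))
    if (validate) {
      m50 <- validate_map50(model, val_dataset)
      if (!is.na(m50) && m50 > best$mAP50)
        best <- list(mAP50 = m50, state = model_state(model))
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss = ep[["loss"]], box = ep[["box"]],
      cls = ep[["cls"]], dfl = ep[["dfl"]], lr = lr, mAP50 = m50))
  }
  if (!is.null(best$state) && is.finite(best$mAP50))
    restore_state(model, best$state)
  list(model = model, history = history, best_mAP50 = best$mAP50)
}

# PBM draw inside the training loop (instrumented; never called at inference)
sample_variation_internal <- function(stats, sigma) {
  counter_bump("sample_variation")
  sample_variation(stats, sigma)
}

validate_map50 <- function(model, val_dataset, conf_threshold = 0.05) {
  dets <- NULL
  for (id in val_dataset$images$id) {
    img <- load_image(val_dataset, id)
    d <- predict_image(model, img, conf_threshold = conf_threshold)
    if (nrow(d) > 0) dets <- rbind(dets, cbind(image_id = id, d))
  }
  if (is.null(dets))
    dets <- data.frame(image_id = numeric(0), category = integer(0),
                       confidence = numeric(0), x1 = numeric(0),
                       y1 = numeric(0), x2 = numeric(0), y2 = numeric(0))
  gt <- val_dataset$annotations
  rep <- evaluate_detections(dets, gt, iou_thresholds = 0.5)
  if (isTRUE(rep$mAP_undefined)) NA_real_ else rep$mAP50
}
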