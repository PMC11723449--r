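# Independent oracles shared across test files.

# Brute-force detection evaluator: unvectorized greedy matching and a
# direct loop over ranks for the AP summation. Kept independent of the
# package's vectorized implementation on purpose.
brute_force_map <- function(det, gt, thr) {
  cats <- sort(unique(gt$category))
  aps <- numeric(0)
  for (cat in cats) {
    dc <- det[det$category == cat, , drop = FALSE]
    dc <- dc[order(-dc$confidence, dc$image_id, dc$x1, dc$y1), , drop = FALSE]
    gc <- gt[gt$category == cat, , drop = FALSE]
    used <- rep(FALSE, nrow(gc))
    flags <- logical(nrow(dc))
    if (nrow(dc) > 0) for (i in seq_len(nrow(dc))) {
      best <- -1; bj <- 0
      for (j in seq_len(nrow(gc))) {
        if (used[j] || gc$image_id[j] != dc$image_id[i]) next
        v <- box_iou(as.numeric(dc[i, c("x1", "y1", "x2", "y2")]),
                     as.numeric(gc[j, c("x1", "y1", "x2", "y2")]))
        if (v > best) { best <- v; bj <- j }
      }
      if (bj > 0 && best >= thr) { flags[i] <- TRUE; used[bj] <- TRUE }
    }
    ap <- 0; tp <- 0; r_prev <- 0
    if (length(flags) > 0) for (n in seq_along(flags)) {
      tp <- tp + flags[n]
      r_n <- tp / nrow(gc); p_n <- tp / n
      ap <- ap + (r_n - r_prev) * p_n
      r_prev <- r_n
    }
    aps <- c(aps, ap)
  }
  mean(aps)
}

random_scene <- function(n_img = 2, n_cat = 3) {
  gt <- NULL; det <- NULL
  for (img in seq_len(n_img)) {
    ng <- sample(1:4, 1)
    for (k in seq_len(ng)) {
      x1 <- runif(1, 0, 60); y1 <- runif(1, 0, 60)
      bw <- runif(1, 5, 30); bh <- runif(1, 5, 30)
      cat <- sample(0:(n_cat - 1), 1)
      gt <- rbind(gt, data.frame(image_id = img, category = cat,
                                 x1 = x1, y1 = y1, x2 = x1 + bw, y2 = y1 + bh))
      # jittered detection (sometimes), plus random false positives below
      if (runif(1) < 0.8) {
        j <- runif(4, -6, 6)
        pcat <- rep(0.1, n_cat); pcat[cat + 1] <- 0.8
        det <- rbind(det, data.frame(
          image_id = img, category = sample(0:(n_cat - 1), 1, prob = pcat),
          confidence = runif(1), x1 = x1 + j[1], y1 = y1 + j[2],
          x2 = x1 + bw + j[3], y2 = y1 + bh + j[4]))
      }
    }
    nf <- sample(0:3, 1)
    for (k in seq_len(nf)) {
      x1 <- runif(1, 0, 60); y1 <- runif(1, 0, 60)
      det <- rbind(det, data.frame(image_id = img,
                                   category = sample(0:(n_cat - 1), 1),
                                   confidence = runif(1),
                                   x1 = x1, y1 = y1, x2 = x1 + runif(1, 5, 25),
                                   y2 = y1 + runif(1, 5, 25)))
    }
  }
  det <- det[det$x2 > det$x1 & det$y2 > det$y1, , drop = FALSE]
  list(det = det, gt = gt)
}

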