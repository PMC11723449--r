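# Training machinery: assignment, loss gradients, schedules, determinism.

test_that("a centered GT gets one positive cell at its matching scale", {
  gt <- data.frame(category = 0L, x1 = 24, y1 = 24, x2 = 40, y2 = 40)
  asg <- assign_targets(gt, c(64L, 64L))
  npos <- vapply(asg, nrow, integer(1))
  expect_equal(sum(npos), 1L)
  # 16 px box, ideal stride ~ 4 cells -> scale 1 (stride 8)
  expect_equal(npos[1], 1L)
  a <- asg[[1]]
  expect_equal(c(a$gy, a$gx), c(4L, 4L))  # center (32, 32) / 8 = cell 4
  # distances from the cell center (36, 36) px in stride units
  expect_equal(c(a$l, a$t, a$r, a$b), c(1.5, 1.5, 0.5, 0.5))
})

test_that("two boxes sharing a center cell both stay assigned", {
  gt <- data.frame(category = c(0L, 1L),
                   x1 = c(24, 26), y1 = c(24, 26), x2 = c(40, 38), y2 = c(40, 38))
  asg <- assign_targets(gt, c(64L, 64L))
  expect_equal(sum(vapply(asg, nrow, integer(1))), 2L)
  a <- asg[[1]]
  expect_equal(sort(a$category), c(0L, 1L))
  expect_equal(anyDuplicated(a[, c("gy", "gx")]), 0L)
})

test_that("empty ground truth assigns nothing", {
  asg <- assign_targets(data.frame(), c(64L, 64L))
  expect_equal(sum(vapply(asg, nrow, integer(1))), 0L)
})

test_that("assignment is invariant to GT ordering", {
  set.seed(1)
  gt <- data.frame(category = sample(0:2, 6, TRUE),
                   x1 = runif(6, 0, 30), y1 = runif(6, 0, 30))
  gt$x2 <- gt$x1 + runif(6, 8, 30)
  gt$y2 <- gt$y1 + runif(6, 8, 30)
  ref <- assign_targets(gt, c(64L, 64L))
  canon <- function(asg) lapply(asg, function(a) a[order(a$gy, a$gx), ])
  for (i in 1:50) {
    shuffled <- gt[sample(nrow(gt)), ]
    expect_equal(canon(assign_targets(shuffled, c(64L, 64L))), canon(ref))
  }
})

test_that("PBM off and sigma 0 give bitwise-identical losses", {
  set.seed(2)
  m <- tiny_model(3L)
  x <- rand_feat(3, 64, 64)
  gt <- data.frame(category = 1L, x1 = 10, y1 = 10, x2 = 40, y2 = 44)
  preds <- model_forward(m, x)
  asg <- list(assign_targets(gt, c(64L, 64L)))
  l_null <- compute_loss(preds, asg, 3L, variation = NULL, training = TRUE)
  l_zero <- compute_loss(preds, asg, 3L, variation = rep(0, 3), training = TRUE)
  expect_identical(l_null$loss, l_zero$loss)
  # and a nonzero variation changes the classification component only
  l_var <- compute_loss(preds, asg, 3L, variation = c(1, -1, 2), training = TRUE)
  expect_false(identical(l_var$cls, l_null$cls))
  expect_identical(l_var$box, l_null$box)
  expect_identical(l_var$dfl, l_null$dfl)
  # out of training the variation is ignored entirely
  l_inf <- compute_loss(preds, asg, 3L, variation = c(1, -1, 2), training = FALSE)
  expect_identical(l_inf$loss, l_null$loss)
})

test_that("perfect box predictions drive the box loss to zero", {
  gt <- data.frame(category = 0L, x1 = 20, y1 = 20, x2 = 44, y2 = 44)
  asg1 <- assign_targets(gt, c(64L, 64L))
  a <- asg1[[1]]
  d <- c(a$l, a$t, a$r, a$b)
  expect_equal(d, c(2, 2, 1, 1))  # integer distances by construction
  preds <- lapply(c(8L, 4L, 2L), function(s)
    array(0, dim = c(s, s, 64 + 3, 1)))
  for (side in 1:4) {
    z <- rep(-30, 16)
    z[d[side] + 1] <- 30           # one-hot bin at the exact distance
    preds[[1]][a$gy + 1, a$gx + 1, (side - 1) * 16 + 1:16, 1] <- z
  }
  l <- compute_loss(preds, list(asg1), 3L, NULL, TRUE)
  expect_lt(l$box, 1e-6)
})

test_that("CIoU gradients agree with finite differences at smooth points", {
  # independent value oracle with the aspect weight alpha held fixed, the
  # standard CIoU training convention the implementation follows
  ciou_value <- function(p, g, alpha) {
    iw <- max(min(p[3], g[3]) - max(p[1], g[1]), 0)
    ih <- max(min(p[4], g[4]) - max(p[2], g[2]), 0)
    I <- iw * ih
    U <- (p[3] - p[1]) * (p[4] - p[2]) + (g[3] - g[1]) * (g[4] - g[2]) - I + 1e-9
    rho2 <- ((p[1] + p[3]) / 2 - (g[1] + g[3]) / 2)^2 +
      ((p[2] + p[4]) / 2 - (g[2] + g[4]) / 2)^2
    c2 <- (max(p[3], g[3]) - min(p[1], g[1]))^2 +
      (max(p[4], g[4]) - min(p[2], g[2]))^2 + 1e-9
    v <- 4 / pi^2 * (atan((g[3] - g[1]) / (g[4] - g[2] + 1e-9)) -
                       atan((p[3] - p[1]) / (p[4] - p[2] + 1e-9)))^2
    I / U - rho2 / c2 - alpha * v
  }
  set.seed(3)
  for (trial in 1:20) {
    g <- c(0, 0, runif(1, 4, 8), runif(1, 4, 8))
    p <- g + runif(4, -1.3, 1.3)
    if (p[3] - p[1] < 1 || p[4] - p[2] < 1) next
    r <- bsdnet:::ciou_with_grad(p, g)
    expect_equal(r$ciou, ciou_value(p, g, r$alpha), tolerance = 1e-9)
    eps <- 1e-6
    for (j in 1:4) {
      pp <- p; pp[j] <- pp[j] + eps
      pm <- p; pm[j] <- pm[j] - eps
      num <- (ciou_value(pp, g, r$alpha) - ciou_value(pm, g, r$alpha)) / (2 * eps)
      expect_equal(r$grad[j], num, tolerance = 1e-5)
    }
  }
})

test_that("loss is finite and non-negative on random predictions (fuzz)", {
  set.seed(4)
  for (trial in 1:60) {
    preds <- lapply(c(8L, 4L, 2L), function(s)
      array(rnorm(s * s * 67, sd = 3), dim = c(s, s, 67L, 1L)))
    gt <- data.frame(category = sample(0:2, 2, TRUE),
                     x1 = runif(2, 0, 30), y1 = runif(2, 0, 30))
    gt$x2 <- gt$x1 + runif(2, 5, 30); gt$y2 <- gt$y1 + runif(2, 5, 30)
    l <- compute_loss(preds, list(assign_targets(gt, c(64L, 64L))), 3L,
                      NULL, TRUE)
    v <- bsdnet:::vof(l$loss)
    expect_true(is.finite(v))
    expect_gte(v, 0)
  }
})

test_that("training is reproducible given the seed", {
  ds <- smoke_dataset()
  run <- function() {
    model <- tiny_model(3L, seed = 5L)
    cfg <- train_config(epochs = 2L, batch_size = 4L, augment = FALSE,
                        input_size = c(64L, 64L), mosaic_off_last = 0L,
                        pbm = list(enabled = TRUE, sigma = 4), seed = 5L)
    fit(model, ds, cfg)$history
  }
  expect_identical(run(), run())
})

test_that("mosaic is disabled for the final mosaic_off_last epochs", {
  ds <- smoke_dataset()
  model <- tiny_model(3L, seed = 6L)
  bsd_counter_reset("mosaic")
  cfg <- train_config(epochs = 12L, batch_size = 8L, augment = TRUE,
                      input_size = c(64L, 64L), mosaic_off_last = 10L,
                      pbm = list(enabled = FALSE), seed = 6L)
  fit(model, ds, cfg)
  # 12 epochs, mosaic active in the first 2 only: 2 epochs x 8 images
  expect_identical(bsd_counter("mosaic"), 16L)
  expect_error(train_config(epochs = 5L, mosaic_off_last = 10L),
               "mosaic_off_last")
})

test_that("PBM is sampled once per batch in training and never at evaluation", {
  ds <- smoke_dataset()
  model <- tiny_model(3L, seed = 7L)
  bsd_counter_reset("sample_variation")
  cfg <- train_config(epochs = 3L, batch_size = 4L, augment = FALSE,
                      input_size = c(64L, 64L), mosaic_off_last = 0L,
                      pbm = list(enabled = TRUE, sigma = 4), seed = 7L)
  fit(model, ds, cfg)
  expect_identical(bsd_counter("sample_variation"), 3L * 2L)  # 2 batches/epoch
  bsd_counter_reset("sample_variation")
  bsdnet:::validate_map50(model, ds)
  expect_identical(bsd_counter("sample_variation"), 0L)
})

test_that("the default recipe echoes the reference settings", {
  cfg <- train_config()
  expect_equal(cfg$epochs, 100L)
  expect_equal(cfg$batch_size, 16L)
  expect_equal(cfg$lr0, 0.01)
  expect_equal(cfg$momentum, 0.937)
  expect_equal(cfg$mosaic_off_last, 10L)
})
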