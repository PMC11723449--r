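# The differentiation engine, checked against naive reference
# implementations and finite differences.

naive_conv2d <- function(x, w, b, stride, pad) {
  d <- dim(x); k <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  ho <- (d[1] + 2 * pad - k) %/% stride + 1
  wo <- (d[2] + 2 * pad - k) %/% stride + 1
  y <- array(0, dim = c(ho, wo, cout, d[4]))
  for (n in seq_len(d[4])) for (co in seq_len(cout))
    for (oh in seq_len(ho)) for (ow in seq_len(wo)) {
      acc <- if (length(b)) b[co] else 0
      for (ci in seq_len(cin)) for (kh in seq_len(k)) for (kw in seq_len(k)) {
        ih <- (oh - 1) * stride - pad + kh
        iw <- (ow - 1) * stride - pad + kw
        if (ih >= 1 && ih <= d[1] && iw >= 1 && iw <= d[2])
          acc <- acc + x[ih, iw, ci, n] * w[kh, kw, ci, co]
      }
      y[oh, ow, co, n] <- acc
    }
  y
}

test_that("conv kernel matches a naive reference (stride, padding, bias)", {
  set.seed(1)
  for (case in list(list(k = 3L, s = 1L), list(k = 3L, s = 2L),
                    list(k = 1L, s = 1L), list(k = 5L, s = 1L))) {
    x <- rand_feat(3, 8, 8, n = 2)
    w <- array(rnorm(case$k^2 * 3 * 4), dim = c(case$k, case$k, 3, 4))
    b <- rnorm(4)
    pad <- (case$k - 1L) %/% 2L
    got <- bsdnet:::.conv2d_forward(x, w, b, case$s, pad, 1L)
    expect_equal(got, naive_conv2d(x, w, b, case$s, pad), tolerance = 1e-12)
  }
})

test_that("depthwise (grouped) convolution matches per-channel reference", {
  set.seed(2)
  x <- rand_feat(4, 6, 6)
  w <- array(rnorm(9 * 4), dim = c(3, 3, 1, 4))
  got <- bsdnet:::.conv2d_forward(x, w, numeric(0), 1L, 1L, 4L)
  for (c in 1:4) {
    ref <- naive_conv2d(x[, , c, , drop = FALSE],
                        w[, , , c, drop = FALSE], numeric(0), 1L, 1L)
    expect_equal(got[, , c, , drop = FALSE], ref, tolerance = 1e-12)
  }
})

test_that("conv backward agrees with finite differences", {
  set.seed(3)
  x <- rand_feat(2, 5, 5)
  w <- array(rnorm(9 * 2 * 3, sd = 0.5), dim = c(3, 3, 2, 3))
  b <- rnorm(3)
  gy <- array(rnorm(5 * 5 * 3), dim = c(5, 5, 3, 1))
  r <- bsdnet:::.conv2d_backward(x, w, gy, 1L, 1L, 1L, TRUE, TRUE)
  f <- function(xx, ww, bb) sum(bsdnet:::.conv2d_forward(xx, ww, bb, 1L, 1L, 1L) * gy)
  eps <- 1e-6
  for (j in sample(length(x), 5)) {
    xp <- x; xp[j] <- xp[j] + eps; xm <- x; xm[j] <- xm[j] - eps
    expect_equal(r$gx[j], (f(xp, w, b) - f(xm, w, b)) / (2 * eps), tolerance = 1e-5)
  }
  for (j in sample(length(w), 5)) {
    wp <- w; wp[j] <- wp[j] + eps; wm <- w; wm[j] <- wm[j] - eps
    expect_equal(r$gw[j], (f(x, wp, b) - f(x, wm, b)) / (2 * eps), tolerance = 1e-5)
  }
  expect_equal(r$gb, sapply(1:3, function(c) sum(gy[, , c, ])), tolerance = 1e-9)
})

test_that("same-size max pooling equals brute-force windowed max", {
  set.seed(4)
  x <- rand_feat(2, 7, 9)
  for (k in c(3L, 5L)) {
    pad <- (k - 1L) %/% 2L
    got <- bsdnet:::.maxpool_forward(x, k)$y
    for (h in 1:7) for (w in 1:9) for (c in 1:2) {
      win <- x[max(1, h - pad):min(7, h + pad),
               max(1, w - pad):min(9, w + pad), c, 1]
      expect_equal(got[h, w, c, 1], max(win))
    }
  }
})

test_that("batch norm normalizes batch statistics in training mode", {
  set.seed(5)
  x <- rand_feat(3, 6, 6, n = 4, lim = 3)
  bn <- bsdnet:::new_batchnorm(3)
  y <- bsdnet:::op_batchnorm(x, bn, training = TRUE)
  for (c in 1:3) {
    expect_equal(mean(y[, , c, ]), 0, tolerance = 1e-9)
    expect_equal(sd(as.vector(y[, , c, ])) * sqrt((6 * 6 * 4 - 1) / (6 * 6 * 4)),
                 1, tolerance = 1e-2)  # eps-shrunk unit variance
  }
  # running stats were updated toward the batch
  expect_false(all(bn$running_mean == 0))
})

test_that("composite op chain gradients agree with finite differences", {
  set.seed(6)
  x0 <- rand_feat(2, 4, 4)
  w <- bsdnet:::ag_param(array(rnorm(2 * 2 * 9, sd = 0.5), dim = c(3, 3, 2, 2)))
  run <- function(xa, record) {
    if (record) bsdnet:::ag_start()
    xn <- if (record) bsdnet:::ag_node(xa) else xa
    y <- bsdnet:::op_conv2d(xn, w)
    y <- bsdnet:::op_silu(y)
    y <- bsdnet:::op_gelu(y)
    y <- bsdnet:::op_add(y, if (record) xn else xa)
    y <- bsdnet:::op_mul(y, y)
    s2 <- bsdnet:::op_space_to_depth(y)
    u <- bsdnet:::op_upsample2(s2)
    out <- bsdnet:::op_concat(list(u, u))
    list(node = out, xn = if (record) xn else NULL)
  }
  r <- run(x0, TRUE)
  set.seed(7)
  loss_grad <- array(rnorm(length(bsdnet:::vof(r$node))),
                     dim = dim(bsdnet:::vof(r$node)))
  bsdnet:::ag_backward(r$node, seed = loss_grad)
  gx <- r$xn$grad
  bsdnet:::ag_stop()
  f <- function(xa) sum(bsdnet:::vof(run(xa, FALSE)$node) * loss_grad)
  eps <- 1e-6
  for (j in sample(length(x0), 6)) {
    xp <- x0; xp[j] <- xp[j] + eps
    xm <- x0; xm[j] <- xm[j] - eps
    expect_equal(gx[j], (f(xp) - f(xm)) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("space-to-depth is a value-preserving bijection", {
  set.seed(8)
  x <- rand_feat(3, 6, 8)
  y <- bsdnet:::op_space_to_depth(x)
  expect_equal(dim(y), c(3L, 4L, 12L, 1L))
  expect_equal(length(y), length(x))
  expect_equal(sort(as.vector(y)), sort(as.vector(x)))  # multiset preserved
  expect_identical(bsdnet:::space_to_depth_inverse(y), x)
})
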