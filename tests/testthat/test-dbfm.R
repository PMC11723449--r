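# Dual-branch feature mixer contracts: residual identity, hand-traced
# scalar forward, fuse ordering, space-to-depth behavior, connectivity.

test_that("global branch preserves shape and is the identity when its final conv is zeroed", {
  set.seed(1)
  m <- dbfm_block(32L, 64L, local_width = 16L, local_repeats = 1L,
                  fused_width = 32L)
  x <- rand_feat(32, 16, 16)
  gi <- dbfm_global_branch(m, x)
  expect_equal(dim(gi), dim(x))
  fill_weights(m$modules$gi_pw$params$w, 0)
  fill_weights(m$modules$gi_pw$params$b, 0)
  expect_identical(dbfm_global_branch(m, x), x)  # exact residual
})

test_that("scalar micro-case of the global branch matches a hand trace", {
  # 2 channels, 1x1 spatial, all weights 1, BN neutralized, input x = 1
  m <- dbfm_block(2L, 4L, local_width = 2L, local_repeats = 1L,
                  fused_width = 2L)
  fill_weights(m$modules$gi_expand$params$w, 1)
  bn_identity(m$modules$gi_expand)
  fill_weights(m$modules$gi_dw$params$w, 1)
  fill_weights(m$modules$gi_dw$params$b, 0)
  fill_weights(m$modules$gi_pw$params$w, 1)
  fill_weights(m$modules$gi_pw$params$b, 0)
  x <- array(1, dim = c(1, 1, 2, 1))
  gi <- dbfm_global_branch(m, x)
  # by hand: expand -> each of 4 channels = 2; SiLU(2) = 2*sigmoid(2) = s
  # F1 = F2 = (s, s); depthwise on F1 + 1 at a single pixel = s + 1
  # gate g = GELU(s+1) = (s+1)*pnorm(s+1); product g*s
  # pointwise sums both channels: 2*g*s; residual + 1
  s <- 2 / (1 + exp(-2))
  g <- (s + 1) * pnorm(s + 1)
  expect_equal(as.numeric(gi), rep(2 * g * s + 1, 2), tolerance = 1e-6)
})

test_that("fusion concatenates LD before GI and mixes to the fused width", {
  set.seed(2)
  m <- dbfm_block(32L, 64L, local_width = 32L, local_repeats = 1L,
                  fused_width = 64L)
  ld <- rand_feat(32, 16, 16); gi <- rand_feat(32, 16, 16)
  fd <- dbfm_fuse(m, ld, gi)
  expect_equal(dim(fd), c(16L, 16L, 64L, 1L))
  expect_false(isTRUE(all.equal(fd, dbfm_fuse(m, gi, ld))))  # order matters
  expect_error(dbfm_fuse(m, ld, rand_feat(32, 8, 8)), "spatial")
  # constructed weights: identity on the first 32 channels, zero elsewhere
  m2 <- dbfm_block(32L, 64L, local_width = 32L, local_repeats = 1L,
                   fused_width = 32L)
  w <- array(0, dim = c(1, 1, 64, 32))
  for (c in 1:32) w[1, 1, c, c] <- 1
  m2$modules$fuse$params$w$value <- w
  bn_identity(m2$modules$fuse)
  fd2 <- dbfm_fuse(m2, ld, gi)
  silu <- function(z) z / (1 + exp(-z))
  expect_equal(fd2, silu(ld), tolerance = 1e-10)
})

test_that("space-to-depth collects sub-grids in (0,0),(1,0),(0,1),(1,1) order", {
  x <- array(c(1, 3, 2, 4), dim = c(2, 2, 1, 1))  # [[a,b],[c,d]] = [[1,2],[3,4]]
  y <- bsdnet:::op_space_to_depth(x)
  expect_equal(dim(y), c(1L, 1L, 4L, 1L))
  expect_equal(as.numeric(y), c(1, 3, 2, 4))  # a, c, b, d
  # bijectivity on a larger map
  set.seed(3)
  z <- rand_feat(5, 8, 10)
  expect_identical(bsdnet:::space_to_depth_inverse(bsdnet:::op_space_to_depth(z)), z)
  expect_error(bsdnet:::op_space_to_depth(rand_feat(2, 5, 6)), "even")
})

test_that("the full mixer halves spatial dims and maps to out_channels", {
  set.seed(4)
  m <- dbfm_block(96L, 192L, local_width = 32L, local_repeats = 1L,
                  fused_width = 96L)
  y <- dbfm_forward(m, rand_feat(96, 40, 40))
  expect_equal(dim(y), c(20L, 20L, 192L, 1L))
  expect_true(all(is.finite(y)))
  # deterministic in inference mode
  x <- rand_feat(96, 16, 16)
  expect_identical(dbfm_forward(m, x), dbfm_forward(m, x))
})

test_that("gradient reaches every input element through the mixer", {
  set.seed(5)
  m <- dbfm_block(8L, 16L, local_width = 8L, local_repeats = 1L,
                  fused_width = 8L)
  for (trial in 1:10) {
    x <- rand_feat(8, 8, 8)
    bsdnet:::ag_start()
    xn <- bsdnet:::ag_node(x)
    y <- dbfm_forward(m, xn, training = TRUE)
    g <- array(rnorm(length(bsdnet:::vof(y))), dim = dim(bsdnet:::vof(y)))
    bsdnet:::ag_backward(y, seed = g)
    gx <- xn$grad
    bsdnet:::ag_stop()
    expect_true(all(gx != 0))
  }
})

test_that("a single-pixel perturbation propagates beyond the local footprint in training mode", {
  # spatial coupling in the global branch comes from the batch-normalized
  # expansion: one pixel shifts the batch statistics of every position
  set.seed(6)
  m <- dbfm_block(8L, 16L, local_width = 8L, local_repeats = 1L,
                  fused_width = 8L)
  x <- rand_feat(8, 12, 12)
  g1 <- dbfm_global_branch(m, x, training = TRUE)
  x2 <- x; x2[1, 1, , 1] <- x2[1, 1, , 1] + 0.5
  g2 <- dbfm_global_branch(m, x2, training = TRUE)
  delta <- abs(g1 - g2)
  far <- delta[8:12, 8:12, , ]   # well outside the 3x3 depthwise footprint
  expect_true(mean(far != 0) > 0.5)
})
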