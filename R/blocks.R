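# Convolutional building blocks: Conv-BN-SiLU, the C2F split/stack/concat
# block, and SPPF pooling. Every block is a plain list carrying its parameter
# environments (`$params`) and child blocks (`$modules`), with S3 methods for
# the forward pass (`fwd`) and analytic profiling (`block_flops`).

new_block <- function(type, ..., params = list(), modules = list()) {
  structure(c(list(...), list(params = params, modules = modules)),
            class = c(paste0("bsd_", type), "bsd_block"))
}

#' @keywords internal
fwd <- function(m, x, training = FALSE) UseMethod("fwd")

# MACs for one conv placement; FLOPs = 2 * MACs (multiply-accumulate = 2).
block_flops <- function(m, h, w) UseMethod("block_flops")

init_conv_weight <- function(k, cin_g, cout) {
  sd <- sqrt(2 / (k * k * cin_g))
  array(stats::rnorm(k * k * cin_g * cout, sd = sd), dim = c(k, k, cin_g, cout))
}

new_batchnorm <- function(c, eps = 1e-3, momentum = 0.03) {
  bn <- new.env(parent = emptyenv())
  bn$gamma <- ag_param(rep(1, c))
  bn$beta <- ag_param(rep(0, c))
  bn$running_mean <- rep(0, c)
  bn$running_var <- rep(1, c)
  bn$eps <- eps
  bn$momentum <- momentum
  bn
}

#' Convolution block: conv + optional batch norm + activation
#'
#' The standard unit of the detector: a 2-d convolution ("same" padding),
#' batch normalization and a SiLU activation. Plain linear convolutions
#' (detection-head outputs, pointwise refinements) use `bn = FALSE`,
#' `act = "none"`, `bias = TRUE`.
#'
#' @param cin,cout input/output channel counts.
#' @param k odd kernel size (1, 3 or 5).
#' @param stride 1 or 2.
#' @param groups channel groups; `groups = cin` gives a depthwise convolution.
#' @param bn apply batch normalization.
#' @param act `"silu"`, `"gelu"` or `"none"`.
#' @param bias add a bias term (default: only when `bn` is off).
#' @return a block object usable with the internal forward generic.
#' @keywords internal
conv_block <- function(cin, cout, k = 1L, stride = 1L, groups = 1L,
                       bn = TRUE, act = "silu", bias = !bn) {
  if (!k %in% c(1L, 3L, 5L)) stop("conv_block: kernel must be 1, 3 or 5")
  if (!stride %in% c(1L, 2L)) stop("conv_block: stride must be 1 or 2")
  if (cin %% groups != 0 || cout %% groups != 0)
    stop("conv_block: channels not divisible by groups")
  params <- list(w = ag_param(init_conv_weight(k, cin %/% groups, cout)))
  if (bias) params$b <- ag_param(rep(0, cout))
  m <- new_block("conv", cin = cin, cout = cout, k = as.integer(k),
                 stride = as.integer(stride), groups = as.integer(groups),
                 act = act, has_bn = bn, params = params)
  if (bn) m$bn <- new_batchnorm(cout)
  m
}

fwd.bsd_conv <- function(m, x, training = FALSE) {
  d <- dim(vof(x))
  if (d[3] != m$cin)
    stop("conv_block: expected ", m$cin, " input channels, got ", d[3])
  if (m$stride == 2L && (d[1] %% 2L != 0L || d[2] %% 2L != 0L))
    stop("conv_block: stride-2 needs even spatial dims, got ", d[1], "x", d[2])
  y <- op_conv2d(x, m$params$w, m$params$b, stride = m$stride, groups = m$groups)
  if (m$has_bn) y <- op_batchnorm(y, m$bn, training = training)
  switch(m$act, silu = op_silu(y), gelu = op_gelu(y), none = y)
}

block_flops.bsd_conv <- function(m, h, w) {
  ho <- if (m$stride == 2L) h %/% 2L else h
  wo <- if (m$stride == 2L) w %/% 2L else w
  macs <- m$k^2 * (m$cin / m$groups) * m$cout * ho * wo
  if (!is.null(m$params$b)) macs <- macs + m$cout * ho * wo
  list(flops = 2 * macs, h = ho, w = wo)
}

# Residual bottleneck used inside C2F: two 3x3 convs, shortcut when the
# channel count is preserved.
bottleneck_block <- function(c, shortcut = TRUE) {
  new_block("bottleneck", c = c, shortcut = shortcut,
            modules = list(cv1 = conv_block(c, c, 3L),
                           cv2 = conv_block(c, c, 3L)))
}

fwd.bsd_bottleneck <- function(m, x, training = FALSE) {
  y <- fwd(m$modules$cv2, fwd(m$modules$cv1, x, training), training)
  if (m$shortcut) op_add(x, y) else y
}

block_flops.bsd_bottleneck <- function(m, h, w) {
  f <- block_flops(m$modules$cv1, h, w)$flops + block_flops(m$modules$cv2, h, w)$flops
  list(flops = f, h = h, w = w)
}

#' C2F block
#'
#' Split the projected input into two halves, push one half through `n`
#' stacked residual bottlenecks, concatenate every intermediate (the 2 + n
#' half-width maps) and fuse with a 1x1 convolution. Hidden width is half the
#' output width.
#'
#' @param cin,cout channel counts; `cout` must be even.
#' @param n number of bottlenecks (>= 1).
#' @param shortcut residual add inside each bottleneck.
#' @keywords internal
c2f_block <- function(cin, cout, n = 1L, shortcut = TRUE) {
  if (n < 1L) stop("c2f_block: n_repeats must be >= 1")
  ch <- cout %/% 2L
  mods <- list(cv1 = conv_block(cin, 2L * ch, 1L))
  for (i in seq_len(n)) mods[[paste0("m", i)]] <- bottleneck_block(ch, shortcut)
  mods$cv2 <- conv_block((2L + n) * ch, cout, 1L)
  new_block("c2f", cin = cin, cout = cout, n = as.integer(n), ch = ch,
            modules = mods)
}

fwd.bsd_c2f <- function(m, x, training = FALSE) {
  y <- fwd(m$modules$cv1, x, training)
  a <- op_slice_ch(y, seq_len(m$ch))
  b <- op_slice_ch(y, m$ch + seq_len(m$ch))
  parts <- list(a, b)
  cur <- b
  for (i in seq_len(m$n)) {
    cur <- fwd(m$modules[[paste0("m", i)]], cur, training)
    parts[[length(parts) + 1L]] <- cur
  }
  fwd(m$modules$cv2, op_concat(parts), training)
}

block_flops.bsd_c2f <- function(m, h, w) {
  f <- sum(vapply(m$modules, function(mm) block_flops(mm, h, w)$flops, numeric(1)))
  list(flops = f, h = h, w = w)
}

#' SPPF block
#'
#' Spatial pyramid pooling (fast): 1x1 squeeze to half width, three cascaded
#' same-size max-pools, concatenation of all four maps, 1x1 fuse.
#'
#' @param cin,cout channel counts.
#' @param k odd pooling kernel (>= 3), default 5.
#' @keywords internal
sppf_block <- function(cin, cout, k = 5L) {
  if (k %% 2L == 0L || k < 3L) stop("sppf_block: pool kernel must be odd >= 3")
  ch <- cin %/% 2L
  new_block("sppf", cin = cin, cout = cout, k = as.integer(k), ch = ch,
            modules = list(cv1 = conv_block(cin, ch, 1L),
                           cv2 = conv_block(4L * ch, cout, 1L)))
}

fwd.bsd_sppf <- function(m, x, training = FALSE) {
  y <- fwd(m$modules$cv1, x, training)
  p1 <- op_maxpool(y, m$k)
  p2 <- op_maxpool(p1, m$k)
  p3 <- op_maxpool(p2, m$k)
  fwd(m$modules$cv2, op_concat(list(y, p1, p2, p3)), training)
}

block_flops.bsd_sppf <- function(m, h, w) {
  f <- block_flops(m$modules$cv1, h, w)$flops + block_flops(m$modules$cv2, h, w)$flops
  list(flops = f, h = h, w = w)  # pooling excluded by convention
}

# --- parameter bookkeeping --------------------------------------------------

# All ag_param environments of a block (recursing into children and BN).
collect_params <- function(m) {
  out <- list()
  if (inherits(m, "bsd_block")) {
    out <- c(out, m$params)
    if (!is.null(m$bn)) out <- c(out, list(m$bn$gamma, m$bn$beta))
    for (child in m$modules) out <- c(out, collect_params(child))
  } else if (is.list(m)) {
    for (child in m) out <- c(out, collect_params(child))
  }
  out
}

n_params <- function(m) {
  sum(vapply(collect_params(m), function(p) length(p$value), numeric(1)))
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
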