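# Tape-based reverse-mode differentiation over (H, W, C, N) feature arrays.
#
# When no tape is active every op returns a plain array (inference fast path).
# With an active tape, ops return `ag_node` environments holding the value and
# a backward closure; ag_backward() replays the tape in reverse. Parameters
# live in `ag_param` environments so gradient accumulation survives R's
# copy-on-modify semantics.

.ag <- new.env(parent = emptyenv())
.ag$on <- FALSE

ag_active <- function() isTRUE(.ag$on)

ag_start <- function() {
  .ag$on <- TRUE
  .ag$tape <- vector("list", 256L)
  .ag$n <- 0L
  invisible(NULL)
}

ag_stop <- function() {
  .ag$on <- FALSE
  .ag$tape <- NULL
  .ag$n <- 0L
  invisible(NULL)
}

ag_node <- function(value, backward = NULL) {
  if (!.ag$on) return(value)
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  class(nd) <- "ag_node"
  n <- .ag$n + 1L
  if (n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
  .ag$tape[[n]] <- nd
  .ag$n <- n
  nd
}

# value-of: unwrap a node or pass an array through
vof <- function(x) if (inherits(x, "ag_node")) x$value else x

ag_accum <- function(x, g) {
  if (inherits(x, "ag_node")) {
    x$grad <- if (is.null(x$grad)) g else x$grad + g
  }
  invisible(NULL)
}

# Run reverse pass from `node` (seed gradient defaults to 1 for scalars).
ag_backward <- function(node, seed = NULL) {
  stopifnot(inherits(node, "ag_node"))
  if (is.null(seed)) seed <- array(1, dim = dim_or1(node$value))
  node$grad <- seed
  for (i in rev(seq_len(.ag$n))) {
    nd <- .ag$tape[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
    .ag$tape[i] <- list(NULL)  # release intermediates as we go
  }
  .ag$n <- 0L
  invisible(NULL)
}

dim_or1 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# --- parameters -------------------------------------------------------------

ag_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  class(p) <- "ag_param"
  p
}

param_accum <- function(p, g) {
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

# --- differentiable ops -----------------------------------------------------

op_conv2d <- function(x, w, b = NULL, stride = 1L, pad = NULL, groups = 1L) {
  xv <- vof(x)
  k <- dim(w$value)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  bias <- if (is.null(b)) numeric(0) else b$value
  y <- .conv2d_forward(xv, w$value, bias, as.integer(stride), as.integer(pad),
                       as.integer(groups))
  if (!.ag$on) return(y)
  force(x); force(w); force(b)
  ag_node(y, function(g) {
    need_gx <- inherits(x, "ag_node")
    r <- .conv2d_backward(xv, w$value, g, as.integer(stride), as.integer(pad),
                          as.integer(groups), need_gx, !is.null(b))
    param_accum(w, r$gw)
    if (!is.null(b)) param_accum(b, r$gb)
    if (need_gx) ag_accum(x, r$gx)
  })
}

# Batch norm. In training mode uses batch statistics and updates the module's
# running estimates in place (momentum as in the YOLO family, eps 1e-3).
op_batchnorm <- function(x, bn, training = FALSE) {
  xv <- vof(x)
  d <- dim(xv)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  if (training) {
    m2 <- matrix(xv, nrow = hw)                  # columns indexed (c, n), c fastest
    cs <- colSums(m2)
    mu <- rowSums(matrix(cs, nrow = C)) / (hw * N)
    cs2 <- colSums(m2 * m2)
    ex2 <- rowSums(matrix(cs2, nrow = C)) / (hw * N)
    v <- pmax(ex2 - mu^2, 0)
    bn$running_mean <- (1 - bn$momentum) * bn$running_mean + bn$momentum * mu
    nb <- hw * N
    bn$running_var <- (1 - bn$momentum) * bn$running_var +
      bn$momentum * v * nb / max(nb - 1, 1)
  } else {
    mu <- bn$running_mean
    v <- bn$running_var
  }
  istd <- 1 / sqrt(v + bn$eps)
  mu_e <- rep(mu, each = hw); istd_e <- rep(istd, each = hw)
  g_e <- rep(bn$gamma$value, each = hw); b_e <- rep(bn$beta$value, each = hw)
  xhat <- (xv - mu_e) * istd_e
  y <- array(xhat * g_e + b_e, dim = d)
  if (!.ag$on) return(y)
  ag_node(y, function(g) {
    gm <- matrix(g * xhat, nrow = hw)
    dgamma <- rowSums(matrix(colSums(gm), nrow = C))
    gb2 <- matrix(g, nrow = hw)
    dbeta <- rowSums(matrix(colSums(gb2), nrow = C))
    param_accum(bn$gamma, dgamma)
    param_accum(bn$beta, dbeta)
    if (inherits(x, "ag_node")) {
      if (training) {
        nb <- hw * N
        dxhat <- g * g_e
        sum_dxhat <- rep(rowSums(matrix(colSums(matrix(dxhat, nrow = hw)), nrow = C)), each = hw)
        sdx <- rowSums(matrix(colSums(matrix(dxhat * xhat, nrow = hw)), nrow = C))
        gx <- istd_e * (dxhat - sum_dxhat / nb - xhat * rep(sdx, each = hw) / nb)
        ag_accum(x, array(gx, dim = d))
      } else {
        ag_accum(x, array(g * g_e * istd_e, dim = d))
      }
    }
  })
}

op_silu <- function(x) {
  xv <- vof(x)
  s <- 1 / (1 + exp(-xv))
  y <- xv * s
  if (!.ag$on) return(y)
  ag_node(y, function(g) {
    if (inherits(x, "ag_node")) ag_accum(x, g * (s * (1 + xv * (1 - s))))
  })
}

# Exact (erf-based) GELU: x * Phi(x).
op_gelu <- function(x) {
  xv <- vof(x)
  Phi <- stats::pnorm(xv)
  y <- xv * Phi
  if (!.ag$on) return(array(y, dim = dim(xv)))
  ag_node(array(y, dim = dim(xv)), function(g) {
    if (inherits(x, "ag_node"))
      ag_accum(x, g * (Phi + xv * stats::dnorm(xv)))
  })
}

op_add <- function(a, b) {
  y <- vof(a) + vof(b)
  if (!.ag$on) return(y)
  ag_node(y, function(g) { ag_accum(a, g); ag_accum(b, g) })
}

op_mul <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  y <- av * bv
  if (!.ag$on) return(y)
  ag_node(y, function(g) { ag_accum(a, g * bv); ag_accum(b, g * av) })
}

# Concatenate along the channel axis (3rd dim).
op_concat <- function(xs) {
  vals <- lapply(xs, vof)
  d1 <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  y <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (i in seq_along(vals)) {
    y[, , at + seq_len(cs[i]), ] <- vals[[i]]
    at <- at + cs[i]
  }
  if (!.ag$on) return(y)
  ag_node(y, function(g) {
    at <- 0L
    for (i in seq_along(xs)) {
      if (inherits(xs[[i]], "ag_node"))
        ag_accum(xs[[i]], g[, , at + seq_len(cs[i]), , drop = FALSE])
      at <- at + cs[i]
    }
  })
}

# Take channels `idx` (contiguous or not) of x.
op_slice_ch <- function(x, idx) {
  xv <- vof(x)
  y <- xv[, , idx, , drop = FALSE]
  if (!.ag$on) return(y)
  ag_node(y, function(g) {
    if (inherits(x, "ag_node")) {
      gx <- array(0, dim = dim(xv))
      gx[, , idx, ] <- g
      ag_accum(x, gx)
    }
  })
}

op_maxpool <- function(x, k) {
  xv <- vof(x)
  r <- .maxpool_forward(xv, as.integer(k))
  if (!.ag$on) return(r$y)
  ag_node(r$y, function(g) {
    if (inherits(x, "ag_node"))
      ag_accum(x, .maxpool_backward(r$idx, g, as.integer(dim(xv))))
  })
}

# Nearest-neighbour 2x upsampling.
op_upsample2 <- function(x) {
  xv <- vof(x)
  d <- dim(xv)
  ri <- rep(seq_len(d[1]), each = 2)
  ci <- rep(seq_len(d[2]), each = 2)
  y <- xv[ri, ci, , , drop = FALSE]
  if (!.ag$on) return(y)
  ag_node(y, function(g) {
    if (inherits(x, "ag_node")) {
      # sum each 2x2 block
      g1 <- g[seq(1, 2 * d[1], 2), , , , drop = FALSE] + g[seq(2, 2 * d[1], 2), , , , drop = FALSE]
      gx <- g1[, seq(1, 2 * d[2], 2), , , drop = FALSE] + g1[, seq(2, 2 * d[2], 2), , , drop = FALSE]
      ag_accum(x, gx)
    }
  })
}

# Four-subregion space-to-depth: (H, W, C, N) -> (H/2, W/2, 4C, N).
# Sub-grid order by (row offset, col offset): (0,0), (1,0), (0,1), (1,1).
op_space_to_depth <- function(x) {
  xv <- vof(x)
  d <- dim(xv)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0)
    stop("space_to_depth: spatial dims must be even, got ", d[1], "x", d[2])
  ro <- list(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
  parts <- lapply(ro, function(o)
    xv[seq(o[1], d[1], 2), seq(o[2], d[2], 2), , , drop = FALSE])
  y <- array(0, dim = c(d[1] / 2, d[2] / 2, 4 * d[3], d[4]))
  for (i in 1:4) y[, , (i - 1) * d[3] + seq_len(d[3]), ] <- parts[[i]]
  if (!.ag$on) return(y)
  ag_node(y, function(g) {
    if (inherits(x, "ag_node")) {
      gx <- array(0, dim = d)
      for (i in 1:4) {
        o <- ro[[i]]
        gx[seq(o[1], d[1], 2), seq(o[2], d[2], 2), , ] <-
          g[, , (i - 1) * d[3] + seq_len(d[3]), , drop = FALSE]
      }
      ag_accum(x, gx)
    }
  })
}

# Inverse of op_space_to_depth (used for the bijectivity contract).
space_to_depth_inverse <- function(y) {
  d <- dim(y)
  C <- d[3] / 4
  x <- array(0, dim = c(d[1] * 2, d[2] * 2, C, d[4]))
  ro <- list(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
  for (i in 1:4) {
    o <- ro[[i]]
    x[seq(o[1], d[1] * 2, 2), seq(o[2], d[2] * 2, 2), , ] <-
      y[, , (i - 1) * C + seq_len(C), , drop = FALSE]
  }
  x
}

# Scalar loss node with an externally supplied gradient router: `grads` is a
# list of (node, grad-array) pairs applied on backward. Used by the training
# loss, whose internals are differentiated in closed form rather than on tape.
op_inject <- function(value, pairs) {
  if (!.ag$on) return(value)
  ag_node(value, function(g) {
    g <- as.numeric(g)[1]
    for (p in pairs) ag_accum(p$node, g * p$grad)
  })
}
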