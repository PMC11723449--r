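# Dual-branch feature mixer (DBFM).
#
# One mixer stage fuses two views of the incoming feature map F:
#   * local-detail branch: a C2F stack, LD = C2F(F);
#   * global-information branch: a gated pointwise/depthwise unit,
#       F1, F2 = Split(SiLU(BN(Conv1x1(F))))         (1x1 expands C -> 2C)
#       GI     = Conv1x1(GELU(DWConv3x3(F1 + F)) * F2) + F
# The branches are concatenated (LD first) and mixed by a 1x1 convolution
# with BN + SiLU into the fused map Fd. Downsampling is done without strided
# convolution: Fd is split into its four even/odd sub-grids, stacked along
# channels (4x), and mixed again by a 1x1 convolution.

#' Construct a dual-branch feature mixer stage
#'
#' @param cin input channels (even, so the expanded map splits evenly).
#' @param cout output channels after space-to-depth mixing.
#' @param local_width output width of the local-detail C2F branch.
#' @param local_repeats number of bottlenecks in the local branch.
#' @param fused_width channel width of the fused dual-branch map.
#' @return a DBFM block; apply with [dbfm_forward()].
#' @export
dbfm_block <- function(cin, cout, local_width = cin, local_repeats = 1L,
                       fused_width = cin) {
  if (cin %% 2L != 0L) stop("dbfm_block: in_channels must be even")
  if (cout < 1L) stop("dbfm_block: out_channels must be >= 1")
  new_block("dbfm", cin = cin, cout = cout, local_width = local_width,
            fused_width = fused_width,
            modules = list(
              local = c2f_block(cin, local_width, local_repeats, shortcut = TRUE),
              gi_expand = conv_block(cin, 2L * cin, 1L),
              gi_dw = conv_block(cin, cin, 3L, groups = cin, bn = FALSE, act = "none"),
              gi_pw = conv_block(cin, cin, 1L, bn = FALSE, act = "none"),
              fuse = conv_block(local_width + cin, fused_width, 1L),
              mix = conv_block(4L * fused_width, cout, 1L)))
}

#' Gated global-information branch
#'
#' Expands the input 1x1 to twice the width, splits into F1/F2, applies a
#' depthwise 3x3 to F1 + F with a GELU gate, multiplies elementwise by F2,
#' refines 1x1 and adds the input back. Output shape equals input shape.
#'
#' @param m a DBFM block from [dbfm_block()].
#' @param x feature array (H, W, C, N) with C equal to the block's `cin`.
#' @param training use batch statistics in BN.
#' @export
dbfm_global_branch <- function(m, x, training = FALSE) {
  cin <- m$cin
  y <- fwd(m$modules$gi_expand, x, training)
  f1 <- op_slice_ch(y, seq_len(cin))
  f2 <- op_slice_ch(y, cin + seq_len(cin))
  gate <- op_gelu(fwd(m$modules$gi_dw, op_add(f1, x), training))
  z <- fwd(m$modules$gi_pw, op_mul(gate, f2), training)
  op_add(z, x)
}

#' Fuse the local-detail and global-information branches
#'
#' Channel-concatenates LD then GI and mixes with a 1x1 conv + BN + SiLU to
#' the block's fused width. Spatial dims must agree.
#'
#' @param m a DBFM block.
#' @param ld,gi feature arrays of identical spatial size.
#' @inheritParams dbfm_global_branch
#' @export
dbfm_fuse <- function(m, ld, gi, training = FALSE) {
  dl <- dim(vof(ld)); dg <- dim(vof(gi))
  if (dl[1] != dg[1] || dl[2] != dg[2])
    stop("dbfm_fuse: spatial dims differ (", dl[1], "x", dl[2], " vs ",
         dg[1], "x", dg[2], ")")
  fwd(m$modules$fuse, op_concat(list(ld, gi)), training)
}

#' Space-to-depth channel mixing
#'
#' Rearranges the fused map into its four strided sub-grids at offsets
#' (0,0), (1,0), (0,1), (1,1) stacked along channels (a lossless bijection:
#' 4c x h/2 x w/2 elements), then mixes channels with a 1x1 convolution.
#'
#' @param m a DBFM block.
#' @param fd fused feature array with even spatial dims.
#' @inheritParams dbfm_global_branch
#' @export
space_to_depth_mix <- function(m, fd, training = FALSE) {
  fwd(m$modules$mix, op_space_to_depth(fd), training)
}

#' Forward pass of a DBFM stage
#'
#' Runs the local and global branches on the input, fuses them, and
#' downsamples by space-to-depth mixing. Output spatial dims are half the
#' input's; output channels are the block's `cout`.
#'
#' @inheritParams dbfm_global_branch
#' @export
dbfm_forward <- function(m, x, training = FALSE) {
  ld <- fwd(m$modules$local, x, training)
  gi <- dbfm_global_branch(m, x, training)
  fd <- dbfm_fuse(m, ld, gi, training)
  space_to_depth_mix(m, fd, training)
}

fwd.bsd_dbfm <- function(m, x, training = FALSE) dbfm_forward(m, x, training)

block_flops.bsd_dbfm <- function(m, h, w) {
  f <- block_flops(m$modules$local, h, w)$flops +
    block_flops(m$modules$gi_expand, h, w)$flops +
    block_flops(m$modules$gi_dw, h, w)$flops +
    block_flops(m$modules$gi_pw, h, w)$flops +
    block_flops(m$modules$fuse, h, w)$flops +
    block_flops(m$modules$mix, h %/% 2L, w %/% 2L)$flops
  list(flops = f, h = h %/% 2L, w = w %/% 2L)
}
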