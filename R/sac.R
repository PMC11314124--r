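# Switchable Atrous Convolution (SAC).
#
# A SAC layer soft-switches, per spatial location, between a dilation-1 and a
# dilation-r convolution that share one kernel: the atrous branch uses exactly
# w + delta_w (the weight lock), never an independent kernel.  The switch S(x)
# is a 5x5 average pool followed by a 1x1 convolution to a single channel and
# a sigmoid; the output is S(x)*Conv(x, w, 1) + (1 - S(x))*Conv(x, w + dw, r).
# Two global-context modules (global average pool -> 1x1 conv -> residual
# broadcast add) flank the switched convolution.

#' Construct SAC parameters
#'
#' Bundles the trainable tensors of one switchable atrous convolution: the
#' shared kernel `w`, the locked offset `delta_w` used by the atrous branch,
#' the switch (1x1 convolution applied after a 5x5 average pool) and the two
#' flanking global-context 1x1 convolutions.
#'
#' @param in_channels,out_channels channel counts.
#' @param k spatial kernel size (odd), default 3.
#' @param r atrous rate of the dilated branch, integer >= 2, default 3.
#' @param init `"zero"` starts delta_w and the switch at zero (S = 0.5, equal
#'   mixing, atrous branch identical to the plain branch); `"random"` draws
#'   Kaiming-uniform values for `w` only (delta_w and switch still zero).
#' @return an object of class `sac_params`.
#' @export
sac_params <- function(in_channels, out_channels, k = 3, r = 3, init = "random") {
  stopifnot(in_channels >= 1, out_channels >= 1, k %% 2 == 1, r >= 2)
  w <- if (init == "zero") matrix(0, in_channels * k * k, out_channels)
       else init_conv_w(in_channels, out_channels, k)
  p <- list(
    w = w,
    delta_w = matrix(0, in_channels * k * k, out_channels),
    switch_w = matrix(0, in_channels, 1L),
    switch_b = 0,
    pre_w = matrix(0, in_channels, in_channels),
    pre_b = numeric(in_channels),
    post_w = matrix(0, out_channels, out_channels),
    post_b = numeric(out_channels),
    k = k, r = r, c1 = in_channels, c2 = out_channels)
  class(p) <- "sac_params"
  p
}

#' Switchable atrous convolution forward pass
#'
#' Computes `S(x) * Conv(x, w, 1) + (1 - S(x)) * Conv(x, w + delta_w, r)` with
#' the one-channel switch broadcast over output channels.  Both branches use
#' "same" padding (the atrous branch pads by `r*(k-1)/2`), so the spatial size
#' is preserved.  Global-context modules are *not* applied here; see
#' [global_context()] and the full SAC layer used inside the network.
#'
#' @param x input array of shape (H, W, C, N).
#' @param params a [sac_params()] object with matching `c1`.
#' @return array (H, W, out_channels, N).
#' @export
sac_forward <- function(x, params) {
  stopifnot(inherits(params, "sac_params"))
  d <- dim(x)
  if (length(d) != 4L || d[3L] != params$c1)
    stop("input must be (H, W, ", params$c1, ", N)")
  if (!identical(dim(params$delta_w), dim(params$w)))
    stop("delta_w shape must match w")
  k <- params$k; r <- params$r
  a <- cpp_avgpool_fw(x, 5L, 1L, 2L)
  z <- cpp_conv2d_fw(a, params$switch_w, params$switch_b, 1L, 1L, 0L, 1L)
  s <- sigmoid(z)
  b1 <- cpp_conv2d_fw(x, params$w, numeric(0), k, 1L, (k - 1) %/% 2, 1L)
  b2 <- cpp_conv2d_fw(x, params$w + params$delta_w, numeric(0), k, 1L,
                      r * (k - 1) %/% 2, r)
  cpp_sac_mix_fw(b1, b2, s)
}

#' Global context module
#'
#' Residual squeeze-and-broadcast: the input is globally average-pooled to one
#' descriptor per channel, passed through a 1x1 convolution, and the result is
#' broadcast-added back onto the input.  With zero weights this is the
#' identity.
#'
#' @param x input array (H, W, C, N).
#' @param w a C x C matrix (1x1 convolution weights; column = output channel).
#' @param b bias vector of length C (default zeros).
#' @return array of the same shape as `x`.
#' @export
global_context <- function(x, w, b = numeric(ncol(w))) {
  d <- dim(x)
  stopifnot(length(d) == 4L, nrow(w) == d[3L], ncol(w) == d[3L])
  p <- gap_fw(x)
  pc <- crossprod(w, p) + b
  bcast_cn(x, pc)
}

## ---- SAC as a network layer (conv + BN + SiLU drop-in) --------------------

mk_sac <- function(c1, c2, k = 3, r = 3, ctx = TRUE) {
  m <- new_module("sac", c1 = c1, c2 = c2, k = k, r = r, ctx = ctx,
                  pad1 = (k - 1) %/% 2, pad2 = r * (k - 1) %/% 2)
  m$params$w <- init_conv_w(c1, c2, k)
  m$params$delta_w <- matrix(0, c1 * k * k, c2)
  m$params$switch_w <- matrix(0, c1, 1L)
  m$params$switch_b <- 0
  if (ctx) {
    m$params$pre_w <- matrix(0, c1, c1)
    m$params$pre_b <- numeric(c1)
    m$params$post_w <- matrix(0, c2, c2)
    m$params$post_b <- numeric(c2)
  }
  m$params$bn_g <- rep(1, c2)
  m$params$bn_b <- numeric(c2)
  m$buffers$rm <- numeric(c2)
  m$buffers$rv <- rep(1, c2)
  m$grads <- zero_like_params(m$params)
  m
}

m_fwd.mod_sac <- function(mod, x, train = FALSE) {
  p <- mod$params
  cc <- list(x = x, train = train)
  x1 <- x
  if (mod$ctx) {
    cc$pool_in <- gap_fw(x)
    pc <- crossprod(p$pre_w, cc$pool_in) + p$pre_b
    x1 <- cpp_add_cn(x, pc)
  }
  cc$xdim <- dim(x1)
  a <- cpp_avgpool_fw(x1, 5L, 1L, 2L)
  z <- cpp_conv2d_fw(a, p$switch_w, p$switch_b, 1L, 1L, 0L, 1L)
  s <- sigmoid(z)
  br <- cpp_sacconv_fw(x1, p$w, p$delta_w, mod$k, mod$r,
                       if (is.null(mod$scc)) NULL else mod$scc)
  mod$scc <- br$cache
  b1 <- br$b1
  b2 <- br$b2
  y0 <- cpp_sac_mix_fw(b1, b2, s)
  cc$a <- a; cc$s <- s; cc$b1 <- b1; cc$b2 <- b2
  if (mod$ctx) {
    cc$pool_out <- gap_fw(y0)
    qc <- crossprod(p$post_w, cc$pool_out) + p$post_b
    y0 <- cpp_add_cn(y0, qc)
  }
  bs <- bn_silu_head(mod, y0, train)
  cc$z <- y0; cc$mu <- bs$mu; cc$istd <- bs$istd
  mod$cache <- cc
  bs$y
}

m_bwd.mod_sac <- function(mod, dout) {
  p <- mod$params
  cc <- mod$cache
  g <- mod$grads
  bnb <- cpp_bn_silu_bw(dout, cc$z, p$bn_g, p$bn_b, cc$mu, cc$istd, cc$train)
  g$bn_g <- g$bn_g + bnb$dg
  g$bn_b <- g$bn_b + bnb$db
  dy0 <- bnb$dx
  if (mod$ctx) {
    dqc <- spatial_csum(dy0)
    g$post_w <- g$post_w + cc$pool_out %*% t(dqc)
    g$post_b <- g$post_b + rowSums(dqc)
    dy0 <- dy0 + gap_bw(p$post_w %*% dqc, dim(dy0))
  }
  mx <- cpp_sac_mix_bw(dy0, cc$b1, cc$b2, cc$s)
  gc2 <- cpp_sacconv_bw(mx$db1, mx$db2, mod$scc, p$w, p$delta_w,
                        mod$k, mod$r, TRUE)
  g$w <- g$w + gc2$dw1 + gc2$dw2
  g$delta_w <- g$delta_w + gc2$dw2
  dz <- mx$ds * cc$s * (1 - cc$s)
  gsw <- cpp_conv2d_bw(cc$a, p$switch_w, dz, 1L, 1L, 0L, 1L, TRUE, TRUE)
  g$switch_w <- g$switch_w + gsw$dw
  g$switch_b <- g$switch_b + gsw$db
  da <- cpp_avgpool_bw(gsw$dx, cc$xdim, 5L, 1L, 2L)
  dx1 <- gc2$dx + da
  if (mod$ctx) {
    dpc <- spatial_csum(dx1)
    g$pre_w <- g$pre_w + cc$pool_in %*% t(dpc)
    g$pre_b <- g$pre_b + rowSums(dpc)
    dx <- dx1 + gap_bw(p$pre_w %*% dpc, dim(dx1))
  } else dx <- dx1
  mod$grads <- g
  dx
}

## ---- C2f-SAC --------------------------------------------------------------

#' Build a C2f-SAC block
#'
#' A C2f block whose input transition convolution is a 3x3 switchable atrous
#' convolution (with flanking global-context modules); the split/concat
#' topology, bottlenecks and output transition stay identical to plain C2f, so
#' spatial size is preserved and the block is a drop-in replacement.
#'
#' @param in_channels,out_channels channel counts (positive).
#' @param n_bottlenecks number of bottleneck units.
#' @param shortcut use residual bottlenecks (TRUE in the backbone).
#' @param r atrous rate of the SAC branch.
#' @return a network module.
#' @export
build_c2f_sac <- function(in_channels, out_channels, n_bottlenecks = 1,
                          shortcut = TRUE, r = 3) {
  stopifnot(in_channels >= 1, out_channels >= 1, n_bottlenecks >= 1)
  c <- out_channels %/% 2
  m <- new_module("c2f_sac", c_hidden = c, n = n_bottlenecks)
  m$children$cv1 <- mk_sac(in_channels, 2 * c, 3, r, ctx = TRUE)
  m$children$cv2 <- mk_convblock((2 + n_bottlenecks) * c, out_channels, 1, 1)
  for (i in seq_len(n_bottlenecks))
    m$children[[paste0("m", i)]] <- mk_bottleneck(c, shortcut)
  class(m) <- c("mod_c2f_sac", "mod_c2f", "lsd_module")
  m
}

# forward/backward inherit the c2f body; cv1 dispatches to the SAC layer
m_fwd.mod_c2f_sac <- function(mod, x, train = FALSE) {
  y0 <- m_fwd(mod$children$cv1, x, train)
  c2f_body(mod, y0, train)
}

m_bwd.mod_c2f_sac <- function(mod, dout) {
  m_bwd(mod$children$cv1, c2f_body_bw(mod, dout))
}
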