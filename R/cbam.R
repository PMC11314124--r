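# Convolutional Block Attention Module (CBAM).
#
# Channel attention: global average- and max-pooled descriptors pass through a
# shared two-layer bottleneck MLP (reduction ratio 8, no biases, ReLU between
# the layers); their sum is squashed by a sigmoid into a per-channel gate.
# Spatial attention: channel-wise mean and max maps are stacked and passed
# through a single 3x3 convolution (2 -> 1 channels) and a sigmoid.  The
# channel gate is applied first, then the spatial map.

#' Construct CBAM parameters
#'
#' @param channels number of input channels C.
#' @param ratio channel reduction ratio of the shared MLP (default 8); the
#'   hidden width is `max(1, C %/% ratio)`.
#' @param init `"zero"` (all-zero weights: both gates are 0.5 everywhere) or
#'   `"random"`.
#' @return an object of class `cbam_params` with fields `w1` (C x C/ratio),
#'   `w2` (C/ratio x C), `spatial_w` (18 x 1) and `spatial_b`.
#' @export
cbam_params <- function(channels, ratio = 8, init = "random") {
  stopifnot(channels >= 1, ratio >= 1)
  h <- max(1L, channels %/% ratio)
  rnd <- function(a, b) matrix(runif(a * b, -sqrt(6 / a), sqrt(6 / a)), a, b)
  p <- list(
    w1 = if (init == "zero") matrix(0, channels, h) else rnd(channels, h),
    w2 = if (init == "zero") matrix(0, h, channels) else rnd(h, channels),
    spatial_w = if (init == "zero") matrix(0, 2 * 9, 1) else rnd(2 * 9, 1),
    spatial_b = 0,
    channels = channels, ratio = ratio, hidden = h)
  class(p) <- "cbam_params"
  p
}

#' Channel attention gate
#'
#' `sigmoid(MLP(avgpool(x)) + MLP(maxpool(x)))` with the MLP shared between
#' the two pooled descriptors.  Returned with singleton spatial dimensions so
#' it broadcasts over H and W.
#'
#' @param x array (H, W, C, N).
#' @param params a [cbam_params()] object.
#' @return array (1, 1, C, N) of gates in (0, 1).
#' @export
channel_attention <- function(x, params) {
  d <- dim(x)
  stopifnot(length(d) == 4L, d[3L] == params$channels)
  pa <- gap_fw(x)
  pm <- gmp_fw(x)$y
  mlp <- function(v) crossprod(params$w2, pmax(crossprod(params$w1, v), 0))
  gate <- sigmoid(mlp(pa) + mlp(pm))
  array(gate, c(1L, 1L, d[3L], d[4L]))
}

#' Spatial attention map
#'
#' `sigmoid(conv3x3(concat(channel-mean, channel-max)))`, one output channel,
#' padding 1, so the spatial size is preserved.
#'
#' @inheritParams channel_attention
#' @return array (H, W, 1, N) with values in (0, 1).
#' @export
spatial_attention <- function(x, params) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  st <- channel_stats(x)
  z <- cpp_conv2d_fw(st$cat, params$spatial_w, params$spatial_b, 3L, 1L, 1L, 1L)
  sigmoid(z)
}

#' CBAM forward pass
#'
#' Applies the channel gate, then the spatial map: `y = (x * Mc) * Ms`.
#' Shape-preserving; every output element is bounded by the input in absolute
#' value since both gates lie in (0, 1).
#'
#' @inheritParams channel_attention
#' @return array of the same shape as `x`.
#' @export
cbam_forward <- function(x, params) {
  gate <- channel_attention(x, params)
  x1 <- mul_cn(x, matrix(gate, dim(x)[3L], dim(x)[4L]))
  ms <- spatial_attention(x1, params)
  x1 * expand_1c(ms, dim(x)[3L])
}

# channel mean / max maps stacked as a 2-channel image, plus argmax bookkeeping
channel_stats <- function(x) cpp_channel_meanmax(x)

## ---- CBAM as a network layer ----------------------------------------------

mk_cbam <- function(C, ratio = 8) {
  h <- max(1L, C %/% ratio)
  m <- new_module("cbam", C = C, hidden = h)
  bound1 <- sqrt(6 / C)
  bound2 <- sqrt(6 / h)
  m$params$w1 <- matrix(runif(C * h, -bound1, bound1), C, h)
  m$params$w2 <- matrix(runif(h * C, -bound2, bound2), h, C)
  m$params$spatial_w <- init_conv_w(2, 1, 3)
  m$params$spatial_b <- 0
  m$grads <- zero_like_params(m$params)
  m
}

m_fwd.mod_cbam <- function(mod, x, train = FALSE) {
  p <- mod$params
  C <- mod$C
  pa <- gap_fw(x)
  pmx <- gmp_fw(x)
  h_a <- pmax(crossprod(p$w1, pa), 0)
  h_m <- pmax(crossprod(p$w1, pmx$y), 0)
  gate <- sigmoid(crossprod(p$w2, h_a) + crossprod(p$w2, h_m))
  x1 <- cpp_mul_cn(x, gate)
  st <- channel_stats(x1)
  z <- cpp_conv2d_fw(st$cat, p$spatial_w, p$spatial_b, 3L, 1L, 1L, 1L)
  ms <- sigmoid(z)
  y <- cpp_mul_bc1(x1, ms)
  mod$cache <- list(x = x, pa = pa, pm = pmx, h_a = h_a, h_m = h_m,
                    gate = gate, x1 = x1, st = st, ms = ms)
  y
}

m_bwd.mod_cbam <- function(mod, dout) {
  p <- mod$params
  cc <- mod$cache
  C <- mod$C
  d <- dim(cc$x)
  dx1 <- cpp_mul_bc1(dout, cc$ms)
  dms <- cpp_sum_mul_over_c(dout, cc$x1)
  dz <- dms * cc$ms * (1 - cc$ms)
  gsp <- cpp_conv2d_bw(cc$st$cat, p$spatial_w, dz, 3L, 1L, 1L, 1L, TRUE, TRUE)
  mod$grads$spatial_w <- mod$grads$spatial_w + gsp$dw
  mod$grads$spatial_b <- mod$grads$spatial_b + gsp$db
  # mean map spreads evenly over channels; max map routes to the argmax channel
  dx1 <- dx1 + cpp_channel_meanmax_bw(gsp$dx, cc$st$argmax, dim(cc$x))
  # channel-gate path
  dgate <- cpp_csum_mul(dx1, cc$x)
  dx <- cpp_mul_cn(dx1, cc$gate)
  dpre <- dgate * cc$gate * (1 - cc$gate)
  dh_a <- p$w2 %*% dpre
  dh_m <- p$w2 %*% dpre
  mod$grads$w2 <- mod$grads$w2 + cc$h_a %*% t(dpre) + cc$h_m %*% t(dpre)
  dva <- p$w1 %*% (dh_a * (cc$h_a > 0))
  dvm <- p$w1 %*% (dh_m * (cc$h_m > 0))
  mod$grads$w1 <- mod$grads$w1 + cc$pa %*% t(dh_a * (cc$h_a > 0)) +
    cc$pm$y %*% t(dh_m * (cc$h_m > 0))
  dx <- dx + gap_bw(dva, d) + gmp_bw(dvm, cc$pm$idx, d)
  dx
}
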