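# Thin R wrappers over the C++ kernels, plus small pooled-descriptor helpers.
# Tensors are (H, W, C, N) numeric arrays.

sigmoid <- function(x) 1 / (1 + exp(-x))

concat_c <- function(xs) cpp_concat_c(xs)

split_c <- function(x, sizes) cpp_split_c(x, as.integer(sizes))

# spatial sum per channel -> (C, N)
spatial_csum <- function(x) cpp_csum_mul(x, numeric(0))

# global average pool over H, W -> (C, N)
gap_fw <- function(x) {
  d <- dim(x)
  cpp_csum_mul(x, numeric(0)) / (d[1L] * d[2L])
}

# scatter a (C, N) gradient of the mean-pooled value back to (H, W, C, N)
gap_bw <- function(dpool, d) {
  hw <- d[1L] * d[2L]
  array(rep(as.numeric(dpool), each = hw) / hw, d)
}

# global max pool over H, W -> list(y = (C, N), idx = argmax row per column)
gmp_fw <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1L] * d[2L], d[3L] * d[4L])
  idx <- max.col(t(m), ties.method = "first")
  y <- m[cbind(idx, seq_len(ncol(m)))]
  list(y = matrix(y, d[3L], d[4L]), idx = idx)
}

gmp_bw <- function(dpool, idx, d) {
  m <- matrix(0, d[1L] * d[2L], d[3L] * d[4L])
  m[cbind(idx, seq_len(ncol(m)))] <- as.numeric(dpool)
  array(m, d)
}

# broadcast helpers used by the exported functional ops
bcast_cn <- function(x, m) cpp_add_cn(x, m)
mul_cn <- function(x, m) cpp_mul_cn(x, m)
expand_1c <- function(s, C) s[, , rep(1L, C), , drop = FALSE]
sum_over_c <- function(g) cpp_sum_mul_over_c(g, array(1, dim(g)))

bn_eps <- 1e-3
bn_momentum <- 0.03
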