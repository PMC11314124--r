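# CBAM: channel and spatial gates, their closed-form degenerate cases,
# parameter accounting and the channel-then-spatial composition order.

test_that("zero-initialised CBAM gates are exactly one half", {
  p <- cbam_params(16, init = "zero")
  set.seed(1)
  x <- array(rnorm(8 * 8 * 16 * 2), c(8, 8, 16, 2))
  expect_equal(as.numeric(channel_attention(x, p)), rep(0.5, 16 * 2))
  expect_equal(as.numeric(spatial_attention(x, p)), rep(0.5, 8 * 8 * 2))
  expect_equal(cbam_forward(x, p), x / 4, tolerance = 1e-12)
})

test_that("spatially constant input makes avg and max descriptors agree", {
  p <- cbam_params(8)
  cvals <- seq(0.1, 0.8, by = 0.1)
  x <- array(rep(cvals, each = 36), c(6, 6, 8, 1))
  gate <- channel_attention(x, p)
  mlp <- function(v) crossprod(p$w2, pmax(crossprod(p$w1, v), 0))
  expected <- 1 / (1 + exp(-2 * mlp(matrix(cvals, 8, 1))))
  expect_equal(as.numeric(gate), as.numeric(expected), tolerance = 1e-12)
})

test_that("CBAM parameter counts match the closed forms", {
  # channel branch at C = 256, ratio 8, shared no-bias MLP
  p <- cbam_params(256, ratio = 8)
  expect_identical(length(p$w1) + length(p$w2), 2L * 256L * 32L)
  # spatial branch: 3x3 conv, 2 -> 1 channels, with bias
  expect_identical(length(p$spatial_w) + length(p$spatial_b), 2L * 9L + 1L)
  mod <- mk_cbam(256, 8)
  expect_identical(count_parameters(mod), 2 * 256 * 32 + 2 * 9 + 1)
})

test_that("gating preserves shape and never amplifies", {
  set.seed(2)
  p <- cbam_params(12)
  x <- array(rnorm(5 * 7 * 12 * 3), c(5, 7, 12, 3))
  y <- cbam_forward(x, p)
  expect_equal(dim(y), dim(x))
  expect_true(all(abs(y) <= abs(x) + 1e-12))
  ms <- spatial_attention(x, p)
  expect_equal(dim(ms), c(5L, 7L, 1L, 3L))
  expect_true(all(ms > 0 & ms < 1))
})

test_that("the composition order is channel gate first, then spatial map", {
  set.seed(3)
  p <- cbam_params(6)
  x <- array(rnorm(4 * 4 * 6 * 2), c(4, 4, 6, 2))
  # manual composition through the exported branch functions
  gate <- channel_attention(x, p)
  x1 <- x * array(rep(as.numeric(gate), each = 16), dim(x))
  manual <- x1 * array(rep(spatial_attention(x1, p), times = 1),
                       c(4, 4, 1, 2))[, , rep(1, 6), , drop = FALSE]
  expect_equal(cbam_forward(x, p), manual, tolerance = 1e-12)
  # the reversed order differs (regression guard on the ordering)
  ms_first <- spatial_attention(x, p)
  x_sp <- x * ms_first[, , rep(1, 6), , drop = FALSE]
  reversed <- x_sp * array(rep(as.numeric(channel_attention(x_sp, p)), each = 16), dim(x))
  expect_gt(max(abs(cbam_forward(x, p) - reversed)), 1e-6)
})

test_that("the network CBAM layer matches the functional composition", {
  set.seed(4)
  mod <- mk_cbam(8)
  p <- cbam_params(8)
  p$w1 <- mod$params$w1; p$w2 <- mod$params$w2
  p$spatial_w <- mod$params$spatial_w; p$spatial_b <- mod$params$spatial_b
  x <- array(rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2))
  expect_equal(m_fwd(mod, x, FALSE), cbam_forward(x, p), tolerance = 1e-12)
})
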