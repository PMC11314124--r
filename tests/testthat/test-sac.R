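# Switchable atrous convolution: limit identities, interpolation, the
# weight lock, and the global-context residual.

make_sac_input <- function(seed = 3, C = 4, H = 10, N = 2) {
  set.seed(seed)
  array(rnorm(H * H * C * N), c(H, H, C, N))
}

test_that("saturated switch reduces SAC to a single branch", {
  set.seed(2)
  p <- sac_params(4, 6, k = 3, r = 3)
  p$delta_w <- matrix(rnorm(length(p$w), sd = 0.2), nrow(p$w), ncol(p$w))
  x <- make_sac_input()
  # switch conv at zero weights: bias alone drives the sigmoid to saturation
  p$switch_b <- 40
  plain <- cpp_conv2d_fw(x, p$w, numeric(0), 3L, 1L, 1L, 1L)
  expect_lt(max(abs(sac_forward(x, p) - plain)) / max(abs(plain)), 1e-5)
  p$switch_b <- -40
  dilated <- cpp_conv2d_fw(x, p$w + p$delta_w, numeric(0), 3L, 1L, 3L, 3L)
  expect_lt(max(abs(sac_forward(x, p) - dilated)) / max(abs(dilated)), 1e-5)
})

test_that("a 1x1 kernel with zero delta is switch-independent", {
  set.seed(4)
  p <- sac_params(4, 4, k = 1)
  x <- make_sac_input()
  y1 <- sac_forward(x, p)
  p$switch_b <- 25
  p$switch_w[] <- rnorm(length(p$switch_w))
  expect_equal(sac_forward(x, p), y1, tolerance = 1e-12)
})

test_that("SAC output interpolates elementwise between the two branches", {
  set.seed(5)
  p <- sac_params(3, 5)
  p$delta_w[] <- rnorm(length(p$delta_w), sd = 0.3)
  p$switch_w[] <- rnorm(length(p$switch_w), sd = 0.5)
  x <- make_sac_input(seed = 6, C = 3)
  y <- sac_forward(x, p)
  b1 <- cpp_conv2d_fw(x, p$w, numeric(0), 3L, 1L, 1L, 1L)
  b2 <- cpp_conv2d_fw(x, p$w + p$delta_w, numeric(0), 3L, 1L, 3L, 3L)
  lo <- pmin(b1, b2); hi <- pmax(b1, b2)
  expect_true(all(y >= lo - 1e-4 & y <= hi + 1e-4))
})

test_that("the weight lock survives gradient updates", {
  # after any number of steps the dilated kernel is exactly w + delta_w by
  # construction; verify the lock operationally: gradients from the dilated
  # branch reach both w and delta_w identically
  set.seed(7)
  sac <- mk_sac(3, 4, 3, 3, ctx = FALSE)
  sac$params$switch_b <- -30   # all weight on the dilated branch
  x <- make_sac_input(seed = 8, C = 3)
  y <- m_fwd(sac, x, TRUE)
  zero_grads(sac)
  m_bwd(sac, y * 0.1)
  expect_equal(sac$grads$delta_w, sac$grads$w, tolerance = 1e-10)
  # a few simulated steps keep the dilated kernel equal to w + delta_w
  for (i in 1:3) {
    sac$params$w <- sac$params$w - 0.01 * sac$grads$w
    sac$params$delta_w <- sac$params$delta_w - 0.01 * sac$grads$delta_w
  }
  # the dilated kernel is materialised as w + delta_w at use time, so the
  # difference is delta_w up to floating-point rounding of the sum
  eff_dilated <- sac$params$w + sac$params$delta_w
  expect_equal(eff_dilated - sac$params$w, sac$params$delta_w,
               tolerance = 1e-12)
})

test_that("switch output is a strict (0,1) sigmoid map of the right shape", {
  set.seed(9)
  sac <- mk_sac(4, 4)
  sac$params$switch_w[] <- rnorm(4)
  x <- make_sac_input(seed = 10)
  invisible(m_fwd(sac, x, FALSE))
  s <- sac$cache$s
  expect_equal(dim(s), c(10L, 10L, 1L, 2L))
  expect_true(all(s > 0 & s < 1))
})

test_that("global context follows its closed-form examples", {
  set.seed(11)
  x <- make_sac_input(seed = 11, C = 3)
  # zero weights: exact identity
  expect_identical(global_context(x, matrix(0, 3, 3)), x)
  # constant input: the added signal is spatially constant
  xc <- array(rep(c(1, 2, 3), each = 100), c(10, 10, 3, 1))
  w <- matrix(rnorm(9), 3, 3)
  y <- global_context(xc, w)
  expect_equal(max(abs(y[, , 1, 1] - y[1, 1, 1, 1])), 0)
  # random input, identity-scaled weights: y - x is spatially uniform per
  # channel and equals the pooled channel mean
  y2 <- global_context(x, diag(3))
  d <- y2 - x
  for (ci in 1:3) {
    expect_equal(max(abs(d[, , ci, 1] - mean(x[, , ci, 1]))), 0,
                 tolerance = 1e-12)
  }
})

test_that("C2f-SAC preserves spatial size and reduces to plain C2f at S=1", {
  set.seed(12)
  blk <- build_c2f_sac(8, 8, 1, TRUE)
  x <- make_sac_input(seed = 13, C = 8)
  y <- m_fwd(blk, x, FALSE)
  expect_equal(dim(y), dim(x))
  # freeze the switch high and delta to zero: the SAC transition becomes a
  # plain 3x3 conv; a C2f built around that exact conv must agree
  blk$children$cv1$params$switch_b <- 40
  blk$children$cv1$params$delta_w[] <- 0
  blk$children$cv1$params$pre_w[] <- 0
  blk$children$cv1$params$post_w[] <- 0
  y_sac <- m_fwd(blk, x, FALSE)
  ref <- mk_c2f(8, 8, 1, TRUE)
  ref$children$cv1 <- mk_convblock(8, 8, 3, 1)
  ref$children$cv1$params$w <- blk$children$cv1$params$w
  ref$children$cv1$params$bn_g <- blk$children$cv1$params$bn_g
  ref$children$cv1$params$bn_b <- blk$children$cv1$params$bn_b
  ref$children$cv1$buffers <- as.list(blk$children$cv1$buffers)
  for (nm in c("cv2", "m1")) {
    # share the remaining weights
    src <- blk$children[[nm]]
    dst <- ref$children[[nm]]
    if (nm == "m1") {
      for (cv in c("cv1", "cv2")) {
        dst$children[[cv]]$params <- as.list(src$children[[cv]]$params)
        dst$children[[cv]]$buffers <- as.list(src$children[[cv]]$buffers)
      }
    } else {
      dst$params <- as.list(src$params)
      dst$buffers <- as.list(src$buffers)
    }
  }
  y_plain <- m_fwd(ref, x, FALSE)
  expect_lt(max(abs(y_sac - y_plain)) / max(abs(y_plain)), 1e-5)
})
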