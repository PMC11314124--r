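# Architecture-intrinsic properties: exact parameter accounting and the
# multi-scale feature-map shape contract.

test_that("a single conv block has the closed-form parameter count", {
  # 3x3 conv, 3 -> 16 channels, no conv bias, batch-norm affine pair
  cb <- mk_convblock(3, 16, 3, 2)
  expect_identical(count_parameters(cb), 3 * 16 * 9 + 2 * 16)
})

test_that("parameter counts are invariant to input size and batch size", {
  v320 <- model_variant(use_sod = TRUE, input_size = 320)
  v640 <- model_variant(use_sod = TRUE, input_size = 640)
  m320 <- build_model(v320, seed = 0)
  m640 <- build_model(v640, seed = 1)   # different init too
  expect_identical(count_parameters(m320), count_parameters(m640))
})

test_that("C2f-SAC has strictly more parameters than plain C2f", {
  set.seed(1)
  plain <- mk_c2f(64, 64, 1, TRUE)
  sac <- build_c2f_sac(64, 64, 1, TRUE)
  expect_gt(count_parameters(sac), count_parameters(plain))
})

test_that("module deltas add exactly across the ablation grid", {
  counts <- vapply(variant_grid(), function(v)
    count_parameters(build_model(v, seed = 0)), numeric(1))
  d_sac <- counts[["sac"]] - counts[["baseline"]]
  d_sod <- counts[["sod"]] - counts[["baseline"]]
  d_cbam <- counts[["cbam"]] - counts[["baseline"]]
  d_full <- counts[["sac_sod_cbam"]] - counts[["baseline"]]
  # near-additivity within 0.05 M (here the placements make it exact)
  expect_lt(abs(d_full - (d_sac + d_sod + d_cbam)), 5e4)
  # the small-object-only variant is lighter than the baseline
  expect_lt(counts[["sod"]], counts[["baseline"]])
})

test_that("neck output shapes follow the stride arithmetic", {
  v <- model_variant(use_sod = TRUE, input_size = 320)
  m <- build_model(v, seed = 0)
  x <- array(0.5, c(320, 320, 3, 2))
  ff <- forward_features(m, x)
  expect_named(ff, c("P2", "P3", "P4", "P5"))
  expect_equal(dim(ff$P2)[1:2], c(80, 80))    # stride 4
  expect_equal(dim(ff$P3)[1:2], c(40, 40))
  expect_equal(dim(ff$P4)[1:2], c(20, 20))
  expect_equal(dim(ff$P5)[1:2], c(10, 10))
  expect_equal(dim(ff$P2)[4], 2)
  # baseline at the same input: three levels, P3-P5 sizes unchanged
  mb <- build_model(model_variant(input_size = 320), seed = 0)
  fb <- forward_features(mb, x)
  expect_named(fb, c("P3", "P4", "P5"))
  expect_equal(dim(fb$P3)[1:2], c(40, 40))
  expect_equal(dim(fb$P5)[1:2], c(10, 10))
})

test_that("forward rejects inputs not divisible by the maximum stride", {
  m <- build_model(model_variant(input_size = 320), seed = 0)
  x <- array(0, c(100, 100, 3, 1))
  expect_error(forward_features(m, x), "divisible")
  expect_error(forward_features(m, array(0, c(64, 64, 4, 1))), "H, W, 3")
})

test_that("forward on a fixed seeded input is reproducible", {
  v <- model_variant(use_sac = TRUE, use_cbam = TRUE, input_size = 64)
  m1 <- build_model(v, seed = 11)
  m2 <- build_model(v, seed = 11)
  set.seed(5)
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3, 1))
  expect_identical(forward_features(m1, x), forward_features(m2, x))
})
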