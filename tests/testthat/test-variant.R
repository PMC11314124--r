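test_that("the three flags span exactly eight distinct variants", {
  grid <- variant_grid()
  expect_length(grid, 8L)
  keys <- vapply(grid, function(v)
    paste(v$use_sac, v$use_sod, v$use_cbam), character(1))
  expect_length(unique(keys), 8L)
  expect_false(grid$baseline$use_sac || grid$baseline$use_sod ||
                 grid$baseline$use_cbam)
  expect_true(grid$sac_sod_cbam$use_sac && grid$sac_sod_cbam$use_sod &&
                grid$sac_sod_cbam$use_cbam)
})

test_that("variant validation rejects bad configurations", {
  expect_error(model_variant(num_classes = 0), "num_classes")
  expect_error(model_variant(input_size = 100), "divisible")
  expect_error(model_variant(use_sod = TRUE, input_size = 96), "64")
  expect_error(model_variant(depth_multiple = 0), "scale")
  expect_error(model_variant(sac_rate = 1), "sac_rate")
  # 96 is a multiple of 32, fine without the P2 head
  expect_s3_class(model_variant(input_size = 96), "lsd_variant")
})

test_that("variant YAML round-trips including placement lists", {
  v <- model_variant(use_sac = TRUE, use_cbam = TRUE, input_size = 320,
                     sac_rate = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_variant(v, path)
  v2 <- read_variant(path)
  expect_equal(v2$sac_rate, 5L)
  expect_equal(v2$input_size, 320L)
  expect_equal(v2$sac_placement, v$sac_placement)
  expect_equal(v2$cbam_placement, v$cbam_placement)
})
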