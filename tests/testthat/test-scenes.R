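# Synthetic scene generator: determinism, label invariants, render/label
# agreement, dataset writing.

test_that("generation is deterministic under a fixed seed", {
  sp <- scene_spec(width = 320, height = 320, n_targets = 3, seed = 7)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$labels, b$labels)
  expect_identical(a$image, b$image)
  # labels agree whether or not pixels are rendered
  c_ <- generate_scene(sp, render = FALSE)
  expect_null(c_$image)
  expect_identical(c_$labels, a$labels)
})

test_that("class mix and target counts respect the scene description", {
  all_dis <- generate_scene(scene_spec(width = 320, height = 320,
                                       n_targets = 4, frac_diseased = 1,
                                       seed = 2), render = FALSE)
  expect_true(all(all_dis$labels$boxes$class_id == 1L))
  none_dis <- generate_scene(scene_spec(width = 320, height = 320,
                                        n_targets = 4, frac_diseased = 0,
                                        seed = 2), render = FALSE)
  expect_true(all(none_dis$labels$boxes$class_id == 0L))
  counts <- vapply(1:100, function(i)
    nrow(generate_scene(scene_spec(width = 512, height = 512, seed = i),
                        render = FALSE)$labels$boxes), numeric(1))
  expect_true(all(counts >= 1 & counts <= 6))
  expect_gt(length(unique(counts)), 2)   # the count really varies
})

test_that("labels satisfy the normalised-box invariants", {
  for (seed in 1:10) {
    sc <- generate_scene(scene_spec(width = 640, height = 480, seed = seed),
                         render = FALSE)
    b <- sc$labels$boxes
    expect_true(all(b$cx - b$w / 2 >= -1e-9 & b$cx + b$w / 2 <= 1 + 1e-9))
    expect_true(all(b$cy - b$h / 2 >= -1e-9 & b$cy + b$h / 2 <= 1 + 1e-9))
    expect_true(all(b$w > 0 & b$h > 0))
    expect_true(all(b$class_id %in% c(0L, 1L)))
  }
})

test_that("a colour-mask re-detection recovers every ground-truth box", {
  for (seed in c(3, 11, 42)) {
    sc <- generate_scene(scene_spec(width = 512, height = 512, seed = seed))
    expect_true(all(scene_selfcheck(sc$image, sc$labels, iou = 0.8)),
                info = paste("seed", seed))
  }
})

test_that("dataset writing produces usable files, refusing dirty output dirs", {
  dir <- withr::local_tempdir()
  sp <- scene_spec(width = 256, height = 256, seed = 40)
  generate_dataset(6, sp, dir, overwrite = TRUE)
  pngs <- list.files(dir, pattern = "\\.png$")
  txts <- list.files(dir, pattern = "\\.txt$")
  expect_length(pngs, 6L)
  expect_length(txts, 6L)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  mf <- read_manifest(file.path(dir, "manifest.yaml"))
  expect_equal(unlist(mf$names, use.names = FALSE), c("lemon", "disease"))
  expect_error(generate_dataset(2, sp, dir), "not empty")
  # byte-identical label files on regeneration
  h1 <- tools::md5sum(file.path(dir, txts))
  dir2 <- withr::local_tempdir()
  generate_dataset(6, sp, dir2, overwrite = TRUE)
  h2 <- tools::md5sum(file.path(dir2, txts))
  expect_identical(unname(h1), unname(h2))
})

test_that("the tiler covers targets of generated high-resolution scenes", {
  sc <- generate_scene(scene_spec(width = 3000, height = 2000, n_targets = 5,
                                  seed = 77), render = FALSE)
  tiles <- tile_image(sc$labels)
  n_boxes <- sum(vapply(tiles, function(t) nrow(t$boxes), numeric(1)))
  expect_gte(n_boxes, nrow(sc$labels$boxes))
  expect_true(all(vapply(tiles, function(t) t$width == 1024L, logical(1))))
})
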