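# YOLO label files, target-centred tiling, fold planning.

test_that("label files round-trip and de-normalise as documented", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines("1 0.5 0.5 0.1 0.2", path)
  li <- read_yolo_labels(path, c(1000, 800))
  px <- yolo_to_pixels(li$boxes, 1000, 800)
  expect_equal((px$x1 + px$x2) / 2, 500)
  expect_equal((px$y1 + px$y2) / 2, 400)
  expect_equal(px$x2 - px$x1, 100)
  expect_equal(px$y2 - px$y1, 160)
  # write/read round trip to 6 decimals on random boxes
  set.seed(31)
  b <- data.frame(class_id = sample(0:1, 20, TRUE),
                  cx = runif(20, 0.3, 0.7), cy = runif(20, 0.3, 0.7),
                  w = runif(20, 0.01, 0.4), h = runif(20, 0.01, 0.4))
  write_yolo_labels(b, path)
  rd <- read_yolo_labels(path, c(640, 640))
  expect_equal(as.matrix(rd$boxes[-1]), as.matrix(b[-1]), tolerance = 1e-6)
  expect_identical(rd$boxes$class_id, b$class_id)
})

test_that("label validation flags bad lines and missing files warn", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0.5 0.5 0.2 0.2", "1 1.2 0.5 0.1 0.1"), path)
  expect_error(read_yolo_labels(path, c(100, 100)), "line\\(s\\) 2")
  writeLines(character(0), path)
  expect_equal(nrow(read_yolo_labels(path, c(100, 100))$boxes), 0L)
  expect_warning(li <- read_yolo_labels(tempfile(), c(10, 10)), "not found")
  expect_equal(nrow(li$boxes), 0L)
})

test_that("tiling centres the window on the target and regenerates labels", {
  li <- labeled_image(3000, 2000,
                      data.frame(class_id = 1L, cx = 0.5, cy = 0.5,
                                 w = 100 / 3000, h = 80 / 2000))
  tiles <- tile_image(li)
  expect_length(tiles, 1L)
  expect_equal(c(tiles[[1]]$x_off, tiles[[1]]$y_off), c(988L, 488L))
  b <- tiles[[1]]$boxes
  expect_equal(as.numeric(b[1, ]), c(1, 0.5, 0.5, 0.09765625, 0.078125))
  expect_false(tiles[[1]]$edge_flags[1])
})

test_that("small images pass through untiled", {
  li <- labeled_image(800, 600,
                      data.frame(class_id = 0L, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2))
  tiles <- tile_image(li)
  expect_length(tiles, 1L)
  expect_equal(tiles[[1]]$width, 800L)
  expect_equal(tiles[[1]]$boxes$cx, 0.5)
})

test_that("tiling round-trips exactly and covers all visible targets", {
  for (seed in 1:12) {
    sc <- generate_scene(scene_spec(width = 3000, height = 2000,
                                    seed = 700 + seed), render = FALSE)
    li <- sc$labels
    px <- yolo_to_pixels(li$boxes, li$width, li$height)
    tiles <- tile_image(li, min_visibility = 0.3)
    covered <- rep(FALSE, nrow(px))
    for (tl in tiles) {
      tb <- yolo_to_pixels(tl$boxes, tl$width, tl$height)
      tb$x1 <- tb$x1 + tl$x_off; tb$x2 <- tb$x2 + tl$x_off
      tb$y1 <- tb$y1 + tl$y_off; tb$y2 <- tb$y2 + tl$y_off
      for (j in seq_len(nrow(tb))) {
        hit <- which(abs(px$x1 - tb$x1[j]) < 1e-6 & abs(px$y1 - tb$y1[j]) < 1e-6 &
                     abs(px$x2 - tb$x2[j]) < 1e-6 & abs(px$y2 - tb$y2[j]) < 1e-6 &
                     px$class_id == tb$class_id[j])
        if (!tl$edge_flags[j]) {
          # un-flagged boxes reproduce the source pixel box exactly
          expect_length(hit, 1L)
          covered[hit] <- TRUE
        }
      }
    }
    # every box appears un-clipped in at least one tile (window is centred
    # on it), hence full coverage at any visibility threshold
    expect_true(all(covered))
  }
})

test_that("fold plans partition the images with balanced, stratified folds", {
  ids <- sprintf("im%04d", 1:2022)
  dis <- rep(c(TRUE, rep(FALSE, 5)), length.out = 2022)
  plan <- make_folds(ids, k = 5, seed = 4, diseased = dis)
  sizes <- as.integer(table(plan$assignment))
  expect_equal(sort(sizes, decreasing = TRUE), c(405L, 405L, 404L, 404L, 404L))
  expect_setequal(names(plan$assignment), ids)
  expect_true(all(plan$assignment %in% 1:5))
  # stratification: every fold holds diseased-positive images
  per_fold_dis <- tapply(dis, plan$assignment[ids], sum)
  expect_true(all(per_fold_dis >= 60))
  # determinism
  expect_identical(plan, make_folds(ids, k = 5, seed = 4, diseased = dis))
  expect_false(identical(plan$assignment,
                         make_folds(ids, k = 5, seed = 5, diseased = dis)$assignment))
  expect_error(make_folds(ids[1:3], k = 5), "exceeds")
})

test_that("instance bookkeeping sums to the dataset totals per fold", {
  set.seed(6)
  ids <- sprintf("t%02d", 1:20)
  boxes <- setNames(lapply(ids, function(i) {
    n <- sample(1:6, 1)
    data.frame(class_id = sample(0:1, n, TRUE, prob = c(0.85, 0.15)))
  }), ids)
  plan <- make_folds(ids, k = 5, seed = 1,
                     diseased = vapply(boxes, function(b) any(b$class_id == 1),
                                       logical(1)))
  tab <- fold_instance_table(plan, boxes, c("lemon", "disease"))
  totals <- c(sum(vapply(boxes, function(b) sum(b$class_id == 0), numeric(1))),
              sum(vapply(boxes, function(b) sum(b$class_id == 1), numeric(1))))
  for (f in 1:5) {
    sub <- tab[tab$fold == f, ]
    expect_equal(sub$lemon[sub$split == "train"] + sub$lemon[sub$split == "val"],
                 totals[1])
    expect_equal(sub$disease[sub$split == "train"] + sub$disease[sub$split == "val"],
                 totals[2])
  }
})
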