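# NMS and prediction decoding.

test_that("NMS suppresses duplicates and keeps disjoint boxes", {
  # identical geometry: only the higher-confidence box survives
  d <- det_df(c(0, 0.9, 0, 0, 10, 10), c(0, 0.8, 0, 0, 10, 10))
  out <- nms_boxes(d, 0.5)
  expect_equal(nrow(out), 1L)
  expect_equal(out$conf, 0.9)
  # disjoint boxes both survive
  d2 <- det_df(c(0, 0.9, 0, 0, 10, 10), c(0, 0.8, 50, 50, 60, 60))
  expect_equal(nrow(nms_boxes(d2, 0.5)), 2L)
  # same geometry, different classes: class-wise NMS keeps both
  d3 <- det_df(c(0, 0.9, 0, 0, 10, 10), c(1, 0.8, 0, 0, 10, 10))
  expect_equal(nrow(nms_boxes(d3, 0.5)), 2L)
})

test_that("greedy NMS on an overlap chain keeps the ends", {
  # A overlaps B (IoU 0.6), B overlaps C (IoU 0.6), A and C overlap weakly;
  # confidences 0.9 / 0.8 / 0.7: greedy keeps A, drops B, keeps C
  A <- c(0, 0, 10, 10)
  B <- c(2.5, 0, 12.5, 10)
  C <- c(2.5, 2.5, 12.5, 12.5)
  expect_equal(box_iou_pair(A, B), 0.6)
  expect_equal(box_iou_pair(B, C), 0.6)
  expect_lt(box_iou_pair(A, C), 0.5)
  d <- det_df(c(0, 0.9, A[1], A[2], A[3], A[4]),
              c(0, 0.8, B[1], B[2], B[3], B[4]),
              c(0, 0.7, C[1], C[2], C[3], C[4]))
  out <- nms_boxes(d, 0.5)
  expect_equal(sort(out$conf), c(0.7, 0.9))
})

test_that("decoding respects thresholds, geometry and the canvas", {
  set.seed(21)
  # one-level synthetic head: 4x4 grid at stride 8 (32 px canvas)
  nc <- 2L; reg_max <- 16L
  box <- array(rnorm(4 * 4 * 4 * reg_max, sd = 0.1), c(4, 4, 4 * reg_max, 1))
  cls <- array(-8, c(4, 4, nc, 1))
  cls[2, 3, 1, 1] <- 4       # one confident cell, class 0
  head <- list(list(box = box, cls = cls))
  det <- decode_predictions(head, conf_threshold = 0.25, iou_threshold = 0.7,
                            strides = 8L, reg_max = reg_max)
  expect_length(det, 1L)
  d <- det[[1L]]
  expect_true(all(d$conf >= 0.25))
  expect_true(all(d$class_id == 0L))
  expect_true(all(d$x1 < d$x2 & d$y1 < d$y2))
  expect_true(all(d$x1 >= 0 & d$x2 <= 32 & d$y1 >= 0 & d$y2 <= 32))
  # centred DFL logits give symmetric distances: the cell centre must sit
  # inside the decoded box, near cell (row 2, col 3)
  expect_true(d$x1[1] < 2.5 * 8 && d$x2[1] > 2.5 * 8)
  expect_true(d$y1[1] < 1.5 * 8 && d$y2[1] > 1.5 * 8)
  # nothing above a threshold no cell can reach
  det2 <- decode_predictions(head, conf_threshold = 0.999, iou_threshold = 0.7,
                             strides = 8L, reg_max = reg_max)
  expect_equal(nrow(det2[[1L]]), 0L)
  expect_error(decode_predictions(head, conf_threshold = 0, iou_threshold = 0.7,
                                  strides = 8L), "thresholds")
  expect_equal(decode_predictions(list()), list())
})

test_that("letterboxing preserves aspect ratio and pads with grey", {
  img <- array(runif(60 * 100 * 3), c(60, 100, 3))
  lb <- letterbox_image(img, 64)
  expect_equal(dim(lb$image), c(64, 64, 3))
  expect_equal(lb$scale, 64 / 100)
  # top band is padding
  expect_true(all(abs(lb$image[1:12, , ] - 114 / 255) < 1e-12))
  # a source corner maps inside the canvas
  expect_true(lb$pad[["y"]] + 60 * lb$scale <= 64 + 1e-9)
})
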