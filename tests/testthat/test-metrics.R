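# Matching, precision/recall, average precision (with brute-force oracle),
# mAP over the threshold range, fold aggregation, error rendering.

test_that("greedy matching handles the canonical cases", {
  # perfect overlap above threshold
  mr <- match_detections(det_df(c(0, 0.9, 0, 0, 10, 10)),
                         gt_df(c(0, 0, 0, 10, 10)), 0.5)
  expect_equal(c(mr$tp, mr$fp, mr$fn), c(1, 0, 0))
  # overlap below threshold: the detection and the target both count against
  mr2 <- match_detections(det_df(c(0, 0.9, 0, 0, 10, 3)),
                          gt_df(c(0, 0, 0, 10, 10)), 0.5)
  expect_equal(c(mr2$tp, mr2$fp, mr2$fn), c(0, 1, 1))
  # two detections on one target: one TP, one FP (one-to-one matching)
  mr3 <- match_detections(det_df(c(0, 0.9, 0, 0, 10, 6),
                                 c(0, 0.8, 0, 1, 10, 7)),
                          gt_df(c(0, 0, 0, 10, 10)), 0.5)
  expect_equal(c(mr3$tp, mr3$fp, mr3$fn), c(1, 1, 0))
  expect_equal(mr3$det_status, c("TP", "FP"))
  # class mismatch is never a match
  mr4 <- match_detections(det_df(c(1, 0.9, 0, 0, 10, 10)),
                          gt_df(c(0, 0, 0, 10, 10)), 0.5)
  expect_equal(c(mr4$tp, mr4$fp, mr4$fn), c(0, 1, 1))
})

test_that("precision and recall reproduce their definitions from counts", {
  dets <- det_df(c(0, 0.9, 0, 0, 10, 10), c(0, 0.8, 40, 40, 50, 50),
                 c(0, 0.7, 100, 100, 110, 110))
  gts <- gt_df(c(0, 0, 0, 10, 10), c(0, 40, 40, 50, 50),
               c(0, 70, 70, 80, 80))
  rep <- evaluate_detections(list(dets), list(gts), iou_thrs = 0.5)
  expect_equal(rep$precision, 2 / 3)   # TP / (TP + FP)
  expect_equal(rep$recall, 2 / 3)      # TP / (TP + FN)
})

test_that("average precision equals the brute-force enumerator", {
  # hand-derivable case: [TP@.9, FP@.8] with 2 targets
  expect_equal(average_precision(c(TRUE, FALSE), c(0.9, 0.8), 2), 0.5)
  # trivial cases
  expect_equal(average_precision(TRUE, 0.9, 1), 1.0)
  expect_equal(average_precision(logical(0), numeric(0), 3), 0)
  expect_error(average_precision(TRUE, 0.9, 0), "undefined")
  # property: random small instances against the oracle
  for (seed in 1:200) {
    inst <- random_ap_instance(seed)
    expect_equal(average_precision(inst$is_tp, inst$conf, inst$n_gt),
                 ap_bruteforce(inst$is_tp, inst$conf, inst$n_gt),
                 info = paste("seed", seed))
  }
})

test_that("the 101-point grid stays close to the all-point integral", {
  for (seed in 1:40) {
    inst <- random_ap_instance(seed)
    if (!length(inst$is_tp)) next
    a <- average_precision(inst$is_tp, inst$conf, inst$n_gt)
    g <- average_precision(inst$is_tp, inst$conf, inst$n_gt, method = "interp101")
    expect_lt(abs(a - g), 0.15)
  }
})

test_that("mAP over the threshold range is the plain arithmetic mean", {
  ap <- matrix(seq(1.0, 0.1, by = -0.1), 1, 10)
  expect_equal(map_range(ap), 0.55)
  expect_equal(map_range(matrix(0, 2, 10)), 0)
  expect_equal(map_range(matrix(1, 2, 10)), 1)
})

test_that("a perfect detector scores 1 everywhere", {
  gts <- gt_df(c(0, 0, 0, 10, 10), c(1, 30, 30, 44, 44))
  dets <- cbind(gts[1], conf = c(0.9, 0.8), gts[-1])
  rep <- evaluate_detections(list(dets), list(gts))
  expect_equal(rep$map50, 1)
  expect_equal(rep$map50_95, 1)
})

test_that("mAP is invariant to class relabelling", {
  set.seed(8)
  dets <- det_df(c(0, 0.9, 0, 0, 10, 10), c(1, 0.85, 30, 30, 40, 40),
                 c(0, 0.4, 60, 60, 70, 70), c(1, 0.3, 90, 90, 99, 99))
  gts <- gt_df(c(0, 0, 0, 10, 10), c(1, 30, 30, 40, 40), c(1, 58, 58, 70, 70))
  r1 <- evaluate_detections(list(dets), list(gts))
  swap <- function(d) { d$class_id <- 1L - d$class_id; d }
  r2 <- evaluate_detections(list(swap(dets)), list(swap(gts)))
  expect_equal(r1$map50, r2$map50)
  expect_equal(r1$map50_95, r2$map50_95)
})

test_that("classes without ground truth are excluded from the class mean", {
  dets <- det_df(c(0, 0.9, 0, 0, 10, 10), c(1, 0.8, 30, 30, 40, 40))
  gts <- gt_df(c(0, 0, 0, 10, 10))   # class 1 has no targets
  rep <- evaluate_detections(list(dets), list(gts))
  expect_equal(rep$map50, 1)          # class 0 alone
})

test_that("fold aggregation uses the population standard deviation", {
  fa <- fold_aggregate(1:5)
  expect_equal(fa$mu, 3)
  expect_equal(fa$sigma, sqrt(2))
  expect_equal(fold_aggregate(rep(4.2, 5))$sigma, 0)
  # cross-check against an independent formulation (sample sd rescaled)
  v <- c(87.5, 88.0, 90.0, 86.5, 88.0)
  expect_equal(fold_aggregate(v)$sigma, stats::sd(v) * sqrt(4 / 5))
  expect_equal(fold_aggregate(v)$mu, mean(v))
  expect_error(fold_aggregate(1:4), "exactly 5")
})

test_that("the error rendering colours TP green, FP red, FN blue", {
  img <- array(0, c(60, 60, 3))
  gts <- gt_df(c(0, 10, 10, 30, 30), c(0, 40, 40, 55, 55))
  # perfect detections: only green appears
  dets <- cbind(gts[1], conf = c(0.9, 0.8), gts[-1])
  mr <- match_detections(dets, gts, 0.5)
  out <- render_tp_fp_fn(img, dets, gts, mr)
  expect_gt(sum(out[, , 2] > 0.5), 0)              # green present
  expect_equal(sum(out[, , 3] > 0.5), 0)           # no blue
  expect_equal(sum(out[, , 1] > 0.5), 0)           # no red
  # no detections: all targets blue
  mr2 <- match_detections(empty_detections(), gts, 0.5)
  out2 <- render_tp_fp_fn(img, empty_detections(), gts, mr2)
  expect_gt(sum(out2[, , 3] > 0.5), 0)
  expect_equal(sum(out2[, , 2] > 0.8), 0)
  # an injected spurious detection adds exactly one red box
  dets3 <- rbind(dets, det_df(c(1, 0.7, 2, 40, 12, 50)))
  mr3 <- match_detections(dets3, gts, 0.5)
  expect_equal(sum(mr3$det_status == "FP"), 1)
  out3 <- render_tp_fp_fn(img, dets3, gts, mr3)
  expect_gt(sum(out3[, , 1] > 0.5), 0)
})
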