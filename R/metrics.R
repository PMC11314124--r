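# Detection metrics: greedy one-to-one matching, precision/recall,
# average precision by all-point interpolation with the monotone precision
# envelope, mAP@50 and mAP@50-95, and the 5-fold mean / population standard
# deviation used to report cross-validation stability.

box_iou_matrix <- function(a, b) {
  # a: n x 4, b: m x 4 (x1, y1, x2, y2)
  n <- nrow(a); m <- nrow(b)
  if (!n || !m) return(matrix(0, n, m))
  ix1 <- outer(a[, 1L], b[, 1L], pmax)
  iy1 <- outer(a[, 2L], b[, 2L], pmax)
  ix2 <- outer(a[, 3L], b[, 3L], pmin)
  iy2 <- outer(a[, 4L], b[, 4L], pmin)
  inter <- pmax(0, ix2 - ix1) * pmax(0, iy2 - iy1)
  aa <- (a[, 3L] - a[, 1L]) * (a[, 4L] - a[, 2L])
  ab <- (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L])
  inter / pmax(outer(aa, ab, "+") - inter, .Machine$double.eps)
}

#' Match detections to ground truth
#'
#' Greedy one-to-one matching in order of descending confidence: a detection
#' is a true positive iff it shares the class of, and has IoU at least
#' `iou_thr` with, a not-yet-matched ground-truth box; among those it takes
#' the highest-IoU one (ties broken by ground-truth index).  Unmatched
#' detections are false positives; unmatched ground truths are false
#' negatives.
#'
#' @param dets data.frame with `class_id`, `conf`, `x1`, `y1`, `x2`, `y2`.
#' @param gts data.frame with `class_id`, `x1`, `y1`, `x2`, `y2`.
#' @param iou_thr matching threshold (e.g. 0.5).
#' @return object of class `match_result`: `det_status` ("TP"/"FP" per
#'   detection, in the order of `dets` sorted by descending confidence),
#'   `det_order` (that ordering), `gt_matched`, `matched_iou`, and the
#'   TP/FP/FN counts.
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  ord <- order(-dets$conf)
  nd <- nrow(dets); ng <- nrow(gts)
  det_status <- character(nd)
  matched_iou <- rep(NA_real_, nd)
  det_gt <- rep(NA_integer_, nd)
  gt_taken <- rep(FALSE, ng)
  iou <- box_iou_matrix(as.matrix(dets[ord, c("x1", "y1", "x2", "y2"), drop = FALSE]),
                        as.matrix(gts[, c("x1", "y1", "x2", "y2"), drop = FALSE]))
  for (i in seq_len(nd)) {
    cand <- which(!gt_taken & gts$class_id == dets$class_id[ord[i]] &
                    iou[i, ] >= iou_thr)
    if (length(cand)) {
      best <- cand[which.max(iou[i, cand])]   # which.max: first max = lowest index
      gt_taken[best] <- TRUE
      det_status[i] <- "TP"
      matched_iou[i] <- iou[i, best]
      det_gt[i] <- best
    } else det_status[i] <- "FP"
  }
  res <- list(det_order = ord, det_status = det_status,
              det_conf = dets$conf[ord], det_class = dets$class_id[ord],
              det_gt = det_gt, matched_iou = matched_iou,
              gt_matched = gt_taken,
              tp = sum(det_status == "TP"), fp = sum(det_status == "FP"),
              fn = sum(!gt_taken))
  class(res) <- "match_result"
  res
}

#' Average precision of one class
#'
#' Area under the precision-recall curve: detections are swept by descending
#' confidence, precision is replaced by its monotone (right-to-left maximum)
#' envelope, and the envelope is integrated over recall -- the all-point
#' interpolation of the continuous integral of P over R.  A 101-point grid
#' variant is available for cross-comparison with COCO-style tooling.
#'
#' @param is_tp logical vector: detection is a true positive.
#' @param conf confidence per detection (same length).
#' @param n_gt number of ground-truth boxes of the class (must be >= 1;
#'   classes with no ground truth have undefined AP and are excluded from
#'   mAP by the caller).
#' @param method `"all_point"` (default) or `"interp101"`.
#' @return AP in `[0, 1]`; 0 when there are no detections.
#' @export
average_precision <- function(is_tp, conf, n_gt, method = "all_point") {
  if (n_gt < 1) stop("AP is undefined for a class with no ground truth")
  if (!length(is_tp)) return(0)
  ord <- order(-conf)
  tp <- cumsum(is_tp[ord])
  fp <- cumsum(!is_tp[ord])
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  # monotone envelope from the right
  env <- rev(cummax(rev(precision)))
  if (method == "interp101") {
    grid <- seq(0, 1, by = 0.01)
    pr <- vapply(grid, function(r) {
      ok <- recall >= r
      if (any(ok)) max(env[ok]) else 0
    }, numeric(1))
    return(mean(pr))
  }
  r_prev <- c(0, recall)
  sum((recall - r_prev[-length(r_prev)]) * env)
}

#' Evaluate detections against ground truth over a dataset
#'
#' Computes per-class AP at each IoU threshold in `iou_thrs`, mAP@50,
#' mAP@50-95, and precision/recall at `pr_iou` from the pooled matching.
#' Classes without ground-truth instances are excluded from the class means.
#'
#' @param dets_by_image list of detection data.frames (one per image).
#' @param gts_by_image list of ground-truth data.frames (same length/order).
#' @param iou_thrs IoU thresholds; default `seq(0.5, 0.95, 0.05)`.
#' @param pr_iou threshold used for the reported precision/recall (0.5).
#' @param method AP integration method, see [average_precision()].
#' @return object of class `lsd_eval_report`: `ap` (class x threshold
#'   matrix), `map50`, `map50_95`, `precision`, `recall`, `per_class_ap50`.
#' @export
evaluate_detections <- function(dets_by_image, gts_by_image,
                                iou_thrs = seq(0.5, 0.95, by = 0.05),
                                pr_iou = 0.5, method = "all_point") {
  stopifnot(length(dets_by_image) == length(gts_by_image))
  classes <- sort(unique(unlist(lapply(gts_by_image, function(g) g$class_id))))
  ap <- matrix(NA_real_, length(classes), length(iou_thrs),
               dimnames = list(as.character(classes),
                               sprintf("%.2f", iou_thrs)))
  tp_cnt <- 0; fp_cnt <- 0; fn_cnt <- 0
  # per-image matching at each threshold, pooled over images per class
  for (ti in seq_along(iou_thrs)) {
    thr <- iou_thrs[ti]
    status <- list()
    for (im in seq_along(dets_by_image)) {
      mr <- match_detections(dets_by_image[[im]], gts_by_image[[im]], thr)
      status[[im]] <- data.frame(class_id = mr$det_class, conf = mr$det_conf,
                                 tp = mr$det_status == "TP")
      if (abs(thr - pr_iou) < 1e-9) {
        tp_cnt <- tp_cnt + mr$tp; fp_cnt <- fp_cnt + mr$fp; fn_cnt <- fn_cnt + mr$fn
      }
    }
    pooled <- do.call(rbind, status)
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      n_gt <- sum(vapply(gts_by_image, function(g) sum(g$class_id == cl), numeric(1)))
      if (n_gt == 0) next
      sel <- pooled$class_id == cl
      ap[ci, ti] <- average_precision(pooled$tp[sel], pooled$conf[sel], n_gt, method)
    }
  }
  rep <- list(ap = ap,
              per_class_ap50 = ap[, 1L],
              map50 = mean(ap[, 1L], na.rm = TRUE),
              map50_95 = map_range(ap),
              precision = if (tp_cnt + fp_cnt > 0) tp_cnt / (tp_cnt + fp_cnt) else 0,
              recall = if (tp_cnt + fn_cnt > 0) tp_cnt / (tp_cnt + fn_cnt) else 0,
              counts = c(tp = tp_cnt, fp = fp_cnt, fn = fn_cnt))
  class(rep) <- "lsd_eval_report"
  rep
}

#' @export
print.lsd_eval_report <- function(x, ...) {
  cat(sprintf("<eval> mAP@50 %.4f  mAP@50-95 %.4f  P %.4f  R %.4f\n",
              x$map50, x$map50_95, x$precision, x$recall))
  invisible(x)
}

#' Serialise an evaluation report
#'
#' Writes the report as JSON (full AP matrix and summary scalars) and/or a
#' one-row CSV mirroring the usual results-table layout: per-class AP@50,
#' mAP@50, mAP@50-95, precision, recall.
#'
#' @param report an `lsd_eval_report`.
#' @param json,csv output paths (either may be NULL).
#' @export
write_eval_report <- function(report, json = NULL, csv = NULL) {
  stopifnot(inherits(report, "lsd_eval_report"))
  if (!is.null(json)) {
    jsonlite::write_json(
      list(ap = as.data.frame(report$ap), map50 = report$map50,
           map50_95 = report$map50_95, precision = report$precision,
           recall = report$recall, counts = as.list(report$counts)),
      json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv)) {
    row <- data.frame(t(report$per_class_ap50), map50 = report$map50,
                      map50_95 = report$map50_95,
                      precision = report$precision, recall = report$recall)
    names(row)[seq_along(report$per_class_ap50)] <-
      paste0("ap50_class", rownames(report$ap))
    write.csv(row, csv, row.names = FALSE)
  }
  invisible(report)
}

#' Mean AP over the 0.50-0.95 threshold range
#'
#' Unweighted mean over classes and IoU thresholds, skipping classes with
#' undefined AP (no ground truth).
#'
#' @param ap_matrix class x threshold AP matrix.
#' @return scalar mAP@50-95.
#' @export
map_range <- function(ap_matrix) {
  mean(ap_matrix, na.rm = TRUE)
}

#' Cross-validation fold aggregate
#'
#' Mean and *population* standard deviation (divide by k, not k - 1) of a
#' metric over the k = 5 validation folds, the overall-standard-deviation
#' convention used to report model stability.
#'
#' @param values numeric vector of exactly 5 per-fold values.
#' @return list `mu`, `sigma`.
#' @export
fold_aggregate <- function(values) {
  if (length(values) != 5L) stop("expected exactly 5 fold values")
  mu <- mean(values)
  list(mu = mu, sigma = sqrt(mean((values - mu)^2)))
}

#' Render TP / FP / FN boxes onto an image
#'
#' True positives are drawn green, false positives red, and missed ground
#' truths (false negatives) blue, each with a small class/confidence tag
#' strip, following the conventional error-visualisation colouring.
#'
#' @param image (H, W, 3) array in `[0, 1]`.
#' @param dets,gts the boxes that were matched.
#' @param match a [match_detections()] result for `dets` vs `gts`.
#' @param lwd border thickness in pixels.
#' @param path optional PNG output path.
#' @return the annotated image array (invisibly if `path` given).
#' @export
render_tp_fp_fn <- function(image, dets, gts, match, lwd = 3L, path = NULL) {
  stopifnot(inherits(match, "match_result"))
  img <- image
  draw <- function(img, b, col) {
    H <- dim(img)[1L]; W <- dim(img)[2L]
    x1 <- max(1L, round(b[1L]) + 1L); y1 <- max(1L, round(b[2L]) + 1L)
    x2 <- min(W, round(b[3L])); y2 <- min(H, round(b[4L]))
    if (x2 <= x1 || y2 <= y1) return(img)
    for (t in seq_len(lwd) - 1L) {
      rows <- c(min(y1 + t, H), max(y2 - t, 1L))
      cols <- c(min(x1 + t, W), max(x2 - t, 1L))
      for (ci in 1:3) {
        img[rows, x1:x2, ci] <- col[ci]
        img[y1:y2, cols, ci] <- col[ci]
      }
    }
    img
  }
  green <- c(0, 0.9, 0); red <- c(1, 0.1, 0.1); blue <- c(0.1, 0.2, 1)
  for (i in seq_along(match$det_order)) {
    b <- dets[match$det_order[i], c("x1", "y1", "x2", "y2")]
    img <- draw(img, as.numeric(b),
                if (match$det_status[i] == "TP") green else red)
  }
  fn_idx <- which(!match$gt_matched)
  for (i in fn_idx)
    img <- draw(img, as.numeric(gts[i, c("x1", "y1", "x2", "y2")]), blue)
  if (!is.null(path)) {
    png::writePNG(img, path)
    return(invisible(img))
  }
  img
}
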