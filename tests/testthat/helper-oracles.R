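# Independent oracles and small fixture builders shared across tests.

# Brute-force average precision: enumerate every confidence cut, compute the
# (P, R) point set, then integrate the precision envelope over the sorted
# unique recalls.  Deliberately a different code path from the package's
# cumulative-sweep implementation.
ap_bruteforce <- function(is_tp, conf, n_gt) {
  if (!length(is_tp)) return(0)
  cuts <- sort(unique(conf), decreasing = TRUE)
  pts <- t(vapply(cuts, function(cc) {
    sel <- conf >= cc
    tp <- sum(is_tp[sel])
    c(p = tp / sum(sel), r = tp / n_gt)
  }, numeric(2)))
  recalls <- sort(unique(pts[, "r"]))
  prev <- 0
  ap <- 0
  for (r in recalls) {
    p_env <- max(pts[pts[, "r"] >= r, "p"])
    ap <- ap + (r - prev) * p_env
    prev <- r
  }
  ap
}

# random matching instance: detections with distinct confidences, each either
# a TP or FP, over a class with n_gt ground truths (TP count <= n_gt)
random_ap_instance <- function(seed) {
  set.seed(seed)
  n_gt <- sample(1:4, 1)
  nd <- sample(0:6, 1)
  conf <- runif(nd)
  max_tp <- min(nd, n_gt)
  n_tp <- if (max_tp > 0) sample(0:max_tp, 1) else 0
  is_tp <- rep(FALSE, nd)
  if (n_tp > 0) is_tp[sample(nd, n_tp)] <- TRUE
  list(is_tp = is_tp, conf = conf, n_gt = n_gt)
}

# tiny box data.frames
det_df <- function(...) {
  m <- rbind(...)
  data.frame(class_id = as.integer(m[, 1]), conf = m[, 2], x1 = m[, 3],
             y1 = m[, 4], x2 = m[, 5], y2 = m[, 6])
}

gt_df <- function(...) {
  m <- rbind(...)
  data.frame(class_id = as.integer(m[, 1]), x1 = m[, 2], y1 = m[, 3],
             x2 = m[, 4], y2 = m[, 5])
}

box_iou_pair <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# small fully-labelled training samples from the scene generator
tiny_dataset <- function(n, canvas = 256, seed = 500, ...) {
  lapply(seq_len(n), function(i) {
    sc <- generate_scene(scene_spec(width = canvas, height = canvas,
                                    seed = seed + i, ...))
    list(image = sc$image, boxes = sc$labels$boxes)
  })
}
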