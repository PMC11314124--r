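# Prediction decoding: distribution-focal box regression to edge distances,
# grid + stride mapping to input pixels, confidence filtering and class-wise
# greedy NMS.

# softmax expectation of the reg_max-bin edge distributions
# box: (H, W, 4*reg_max, N) -> list of matrices (A x 4) per image, cell units
dfl_expect <- function(box, reg_max) {
  d <- dim(box)
  A <- d[1L] * d[2L]
  lapply(seq_len(d[4L]), function(n) {
    m <- matrix(box[, , , n], A, 4L * reg_max)
    out <- matrix(0, A, 4L)
    bins <- 0:(reg_max - 1L)
    for (side in 1:4) {
      z <- m[, (side - 1L) * reg_max + seq_len(reg_max), drop = FALSE]
      p <- softmax_rows(z)
      out[, side] <- as.numeric(p %*% bins)
    }
    out
  })
}

# cell centres for a (H, W) grid, flattened h-fastest: (A x 2) = (cx, cy)
grid_centres <- function(H, W) {
  cbind(rep(seq_len(W) - 0.5, each = H), rep(seq_len(H) - 0.5, times = W))
}

#' Decode raw head outputs into detections
#'
#' Applies the distribution-focal softmax expectation to the box branch,
#' maps cell-relative edge distances to input-pixel corners through the grid
#' and stride, sigmoids the class logits, keeps (cell, class) scores at or
#' above `conf_threshold`, and runs class-wise greedy NMS at `iou_threshold`.
#'
#' @param head_outputs list per level of `list(box, cls)` arrays as returned
#'   by the network head.
#' @param conf_threshold,iou_threshold probabilities in (0, 1); conventional
#'   values are 0.25 / 0.7 for prediction and 0.001 / 0.7 for mAP evaluation.
#' @param strides integer vector, one stride per head level.
#' @param reg_max number of DFL bins per box side (16).
#' @param max_det per-class cap on detections per image (300).
#' @return list (one element per image) of data.frames with columns
#'   `class_id`, `conf`, `x1`, `y1`, `x2`, `y2` (pixels, x1 < x2, y1 < y2).
#' @export
decode_predictions <- function(head_outputs, conf_threshold = 0.25,
                               iou_threshold = 0.7, strides = c(8L, 16L, 32L),
                               reg_max = 16L, max_det = 300L) {
  if (conf_threshold <= 0 || conf_threshold >= 1 ||
      iou_threshold <= 0 || iou_threshold >= 1)
    stop("thresholds must lie in (0, 1)")
  if (length(head_outputs) == 0L) return(list())
  stopifnot(length(strides) == length(head_outputs))
  N <- dim(head_outputs[[1L]]$cls)[4L]
  canvas <- dim(head_outputs[[1L]]$cls)[1:2] * strides[1L]  # (H, W) pixels
  out <- vector("list", N)
  for (n in seq_len(N)) {
    rows <- list()
    for (l in seq_along(head_outputs)) {
      s <- strides[l]
      box <- head_outputs[[l]]$box
      cls <- head_outputs[[l]]$cls
      d <- dim(cls)
      A <- d[1L] * d[2L]
      nc <- d[3L]
      conf <- matrix(sigmoid(matrix(cls[, , , n], A, nc)), A, nc)
      keep_cell <- which(row_max(conf) >= conf_threshold)
      if (!length(keep_cell)) next
      e <- dfl_expect(box[, , , n, drop = FALSE], reg_max)[[1L]][keep_cell, , drop = FALSE]
      ctr <- grid_centres(d[1L], d[2L])[keep_cell, , drop = FALSE]
      x1 <- (ctr[, 1L] - e[, 1L]) * s
      y1 <- (ctr[, 2L] - e[, 2L]) * s
      x2 <- (ctr[, 1L] + e[, 3L]) * s
      y2 <- (ctr[, 2L] + e[, 4L]) * s
      for (ci in seq_len(nc)) {
        sel <- conf[keep_cell, ci] >= conf_threshold
        if (!any(sel)) next
        rows[[length(rows) + 1L]] <- data.frame(
          class_id = ci - 1L, conf = conf[keep_cell[sel], ci],
          x1 = x1[sel], y1 = y1[sel], x2 = x2[sel], y2 = y2[sel])
      }
    }
    det <- if (length(rows)) do.call(rbind, rows) else empty_detections()
    # clip to the padded input canvas and drop degenerate boxes
    if (nrow(det)) {
      det$x1 <- pmin(pmax(det$x1, 0), canvas[2L])
      det$x2 <- pmin(pmax(det$x2, 0), canvas[2L])
      det$y1 <- pmin(pmax(det$y1, 0), canvas[1L])
      det$y2 <- pmin(pmax(det$y2, 0), canvas[1L])
      det <- det[det$x2 > det$x1 & det$y2 > det$y1, , drop = FALSE]
    }
    out[[n]] <- nms_boxes(det, iou_threshold, max_det = max_det)
  }
  out
}

empty_detections <- function() {
  data.frame(class_id = integer(0), conf = numeric(0), x1 = numeric(0),
             y1 = numeric(0), x2 = numeric(0), y2 = numeric(0))
}

# IoU of one box against a matrix of boxes (columns x1, y1, x2, y2)
iou_one_many <- function(b, m) {
  iw <- pmax(0, pmin(b[3L], m[, 3L]) - pmax(b[1L], m[, 1L]))
  ih <- pmax(0, pmin(b[4L], m[, 4L]) - pmax(b[2L], m[, 2L]))
  inter <- iw * ih
  a1 <- (b[3L] - b[1L]) * (b[4L] - b[2L])
  a2 <- (m[, 3L] - m[, 1L]) * (m[, 4L] - m[, 2L])
  inter / pmax(a1 + a2 - inter, .Machine$double.eps)
}

#' Class-wise greedy non-maximum suppression
#'
#' Boxes are visited in order of descending confidence; a box is kept unless
#' it overlaps an already-kept box of the same class with IoU strictly above
#' `iou_threshold`.
#'
#' @param det detection data.frame (`class_id`, `conf`, `x1`, `y1`, `x2`, `y2`).
#' @param iou_threshold suppression threshold.
#' @param class_wise suppress within classes only (default) or globally.
#' @param max_det per-class cap, by confidence.
#' @return the surviving subset of `det`, ordered by descending confidence.
#' @export
nms_boxes <- function(det, iou_threshold = 0.7, class_wise = TRUE,
                      max_det = 300L) {
  if (!nrow(det)) return(det)
  groups <- if (class_wise) split(seq_len(nrow(det)), det$class_id)
            else list(seq_len(nrow(det)))
  keep <- integer(0)
  for (idx in groups) {
    sub <- det[idx, , drop = FALSE]
    ord <- order(-sub$conf)
    chosen <- integer(0)
    for (i in ord) {
      b <- c(sub$x1[i], sub$y1[i], sub$x2[i], sub$y2[i])
      if (length(chosen)) {
        m <- as.matrix(sub[chosen, c("x1", "y1", "x2", "y2"), drop = FALSE])
        if (any(iou_one_many(b, m) > iou_threshold)) next
      }
      chosen <- c(chosen, i)
      if (length(chosen) >= max_det) break
    }
    keep <- c(keep, idx[chosen])
  }
  out <- det[keep, , drop = FALSE]
  out[order(-out$conf), , drop = FALSE]
}

#' Letterbox an image to a square canvas
#'
#' Aspect-preserving bilinear resize followed by symmetric padding with the
#' conventional grey value 114/255, so arbitrary images can enter the
#' fixed-size network input.
#'
#' @param img array (H, W, 3) with values in `[0, 1]`.
#' @param size target square edge (pixels).
#' @return list with `image` (size, size, 3), `scale` (source-to-target
#'   factor), and `pad` = c(x, y) offsets of the image content in pixels;
#'   a source pixel (x, y) maps to (x*scale + pad[1], y*scale + pad[2]).
#' @export
letterbox_image <- function(img, size) {
  d <- dim(img)
  stopifnot(length(d) == 3L, d[3L] == 3L)
  scale <- min(size / d[1L], size / d[2L])
  nh <- round(d[1L] * scale)
  nw <- round(d[2L] * scale)
  resized <- resize_bilinear(img, nh, nw)
  canvas <- array(114 / 255, c(size, size, 3L))
  y0 <- floor((size - nh) / 2)
  x0 <- floor((size - nw) / 2)
  canvas[y0 + seq_len(nh), x0 + seq_len(nw), ] <- resized
  list(image = canvas, scale = scale, pad = c(x = x0, y = y0))
}

# plain bilinear resize of an (H, W, C) array
resize_bilinear <- function(img, H2, W2) {
  d <- dim(img)
  ys <- pmin(pmax((seq_len(H2) - 0.5) * d[1L] / H2 - 0.5, 0), d[1L] - 1)
  xs <- pmin(pmax((seq_len(W2) - 0.5) * d[2L] / W2 - 0.5, 0), d[2L] - 1)
  y0 <- pmin(floor(ys), d[1L] - 1); y1 <- pmin(y0 + 1, d[1L] - 1)
  x0 <- pmin(floor(xs), d[2L] - 1); x1 <- pmin(x0 + 1, d[2L] - 1)
  wy <- ys - y0; wx <- xs - x0
  out <- array(0, c(H2, W2, d[3L]))
  for (ci in seq_len(d[3L])) {
    ch <- img[, , ci]
    a <- ch[cbind(rep(y0 + 1, W2), rep(x0 + 1, each = H2))]
    b <- ch[cbind(rep(y0 + 1, W2), rep(x1 + 1, each = H2))]
    cc <- ch[cbind(rep(y1 + 1, W2), rep(x0 + 1, each = H2))]
    dd <- ch[cbind(rep(y1 + 1, W2), rep(x1 + 1, each = H2))]
    wyr <- rep(wy, W2); wxr <- rep(wx, each = H2)
    out[, , ci] <- (1 - wyr) * ((1 - wxr) * a + wxr * b) +
                   wyr * ((1 - wxr) * cc + wxr * dd)
  }
  out
}

#' Detect objects in an image
#'
#' End-to-end convenience wrapper: letterbox the image to the variant's input
#' size, run the network, decode, and map boxes back to source-image pixels.
#'
#' @param model an `lsd_model`.
#' @param img array (H, W, 3) in `[0, 1]`, or a path to a PNG file.
#' @param conf,iou decode thresholds (see [decode_predictions()]).
#' @return a detection data.frame in source-image pixel coordinates.
#' @export
detect_image <- function(model, img, conf = 0.25, iou = 0.7) {
  if (is.character(img)) img <- png::readPNG(img)[, , 1:3, drop = FALSE]
  lb <- letterbox_image(img, model$variant$input_size)
  x <- array(lb$image, c(dim(lb$image), 1L))
  fh <- forward_heads(model, x, train = FALSE)
  det <- decode_predictions(fh$head, conf, iou, strides = model$strides,
                            reg_max = model$reg_max)[[1L]]
  if (nrow(det)) {
    det$x1 <- (det$x1 - lb$pad[["x"]]) / lb$scale
    det$x2 <- (det$x2 - lb$pad[["x"]]) / lb$scale
    det$y1 <- (det$y1 - lb$pad[["y"]]) / lb$scale
    det$y2 <- (det$y2 - lb$pad[["y"]]) / lb$scale
    det$x1 <- pmax(det$x1, 0); det$y1 <- pmax(det$y1, 0)
    det$x2 <- pmin(det$x2, dim(img)[2L]); det$y2 <- pmin(det$y2, dim(img)[1L])
  }
  det
}
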