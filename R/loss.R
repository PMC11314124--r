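# Detection training loss: task-aligned assignment of anchors to ground
# truth, binary cross-entropy classification against soft target scores,
# complete-IoU box regression and distribution-focal edge regression --
# the standard anchor-free stack the detector family inherits unchanged.

tal_topk <- 10L
tal_alpha <- 0.5
tal_beta <- 6.0
gain_box <- 7.5
gain_cls <- 0.5
gain_dfl <- 1.5

# complete IoU between row-aligned boxes (n x 4 each)
ciou_vec <- function(p, g) {
  iw <- pmax(0, pmin(p[, 3L], g[, 3L]) - pmax(p[, 1L], g[, 1L]))
  ih <- pmax(0, pmin(p[, 4L], g[, 4L]) - pmax(p[, 2L], g[, 2L]))
  inter <- iw * ih
  ap <- pmax(p[, 3L] - p[, 1L], 1e-9) * pmax(p[, 4L] - p[, 2L], 1e-9)
  ag <- (g[, 3L] - g[, 1L]) * (g[, 4L] - g[, 2L])
  un <- ap + ag - inter
  iou <- inter / pmax(un, 1e-9)
  # enclosing box diagonal and centre distance
  cw <- pmax(p[, 3L], g[, 3L]) - pmin(p[, 1L], g[, 1L])
  ch <- pmax(p[, 4L], g[, 4L]) - pmin(p[, 2L], g[, 2L])
  c2 <- cw^2 + ch^2 + 1e-9
  rho2 <- ((p[, 1L] + p[, 3L] - g[, 1L] - g[, 3L])^2 +
           (p[, 2L] + p[, 4L] - g[, 2L] - g[, 4L])^2) / 4
  wp <- pmax(p[, 3L] - p[, 1L], 1e-9); hp <- pmax(p[, 4L] - p[, 2L], 1e-9)
  wg <- pmax(g[, 3L] - g[, 1L], 1e-9); hg <- pmax(g[, 4L] - g[, 2L], 1e-9)
  v <- (4 / pi^2) * (atan(wg / hg) - atan(wp / hp))^2
  alpha <- v / (1 - iou + v + 1e-9)
  iou - rho2 / c2 - alpha * v
}

# numeric gradient of sum(w * (1 - ciou)) w.r.t. the 4 predicted coordinates
ciou_loss_grad <- function(p, g, w, h = 0.05) {
  grad <- matrix(0, nrow(p), 4L)
  for (j in 1:4) {
    ph <- p; ph[, j] <- ph[, j] + h
    pl <- p; pl[, j] <- pl[, j] - h
    grad[, j] <- w * (ciou_vec(pl, g) - ciou_vec(ph, g)) / (2 * h)
  }
  grad
}

# flatten head outputs of one image into matrices + anchor geometry
flatten_head <- function(head, n, strides, reg_max, nc) {
  cls <- list(); box <- list(); acx <- list(); acy <- list(); astr <- list()
  for (l in seq_along(head)) {
    d <- dim(head[[l]]$cls)
    A <- d[1L] * d[2L]
    cls[[l]] <- matrix(head[[l]]$cls[, , , n], A, nc)
    box[[l]] <- matrix(head[[l]]$box[, , , n], A, 4L * reg_max)
    ctr <- grid_centres(d[1L], d[2L])
    acx[[l]] <- ctr[, 1L]; acy[[l]] <- ctr[, 2L]
    astr[[l]] <- rep(strides[l], A)
  }
  list(cls = do.call(rbind, cls), box = do.call(rbind, box),
       acx = unlist(acx), acy = unlist(acy), stride = unlist(astr),
       sizes = vapply(head, function(h) prod(dim(h$cls)[1:2]), numeric(1)))
}

row_max <- function(z) {
  m <- z[, 1L]
  for (j in seq_len(ncol(z))[-1L]) m <- pmax(m, z[, j])
  m
}

softmax_rows <- function(z) {
  z <- exp(z - row_max(z))
  z / rowSums(z)
}

#' Detection loss with gradients
#'
#' Task-aligned assigner (top-10 candidates per target among anchors whose
#' centre falls inside the target box, alignment metric
#' `score^0.5 * IoU^6`, conflicts resolved by IoU), then BCE classification
#' against normalised alignment scores, CIoU box loss and distribution-focal
#' loss on the assigned anchors, with the conventional 7.5 / 0.5 / 1.5
#' component gains.
#'
#' @param head raw head outputs (list per level of `list(box, cls)`).
#' @param targets data.frame with `image` (1-based batch index), `class_id`,
#'   and `cx`, `cy`, `w`, `h` normalised to the input canvas.
#' @param strides per-level strides; `input_size` canvas edge in pixels.
#' @param reg_max,nc head geometry.
#' @return list: `total`, `box`, `cls`, `dfl` (scalars), `fg` (assigned
#'   anchor count), and `dhead` (gradient arrays shaped like `head`).
#' @export
compute_loss <- function(head, targets, strides, input_size, reg_max = 16L,
                         nc = 2L) {
  N <- dim(head[[1L]]$cls)[4L]
  bins <- 0:(reg_max - 1L)
  dhead <- lapply(head, function(h)
    list(box = array(0, dim(h$box)), cls = array(0, dim(h$cls))))
  l_cls <- 0; l_box <- 0; l_dfl <- 0; fg_total <- 0L; score_sum_total <- 0
  for (n in seq_len(N)) {
    fl <- flatten_head(head, n, strides, reg_max, nc)
    A <- nrow(fl$cls)
    probs <- sigmoid(fl$cls)
    # decoded boxes in input pixels
    pmat <- matrix(0, A, 4L)
    dexp <- matrix(0, A, 4L)      # softmax expectations per side
    pside <- vector("list", 4L)   # softmax probabilities per side
    for (side in 1:4) {
      z <- fl$box[, (side - 1L) * reg_max + seq_len(reg_max), drop = FALSE]
      p <- softmax_rows(z)
      pside[[side]] <- p
      dexp[, side] <- as.numeric(p %*% bins)
    }
    pmat[, 1L] <- (fl$acx - dexp[, 1L]) * fl$stride
    pmat[, 2L] <- (fl$acy - dexp[, 2L]) * fl$stride
    pmat[, 3L] <- (fl$acx + dexp[, 3L]) * fl$stride
    pmat[, 4L] <- (fl$acy + dexp[, 4L]) * fl$stride

    tgt <- targets[targets$image == n, , drop = FALSE]
    tscore <- matrix(0, A, nc)
    fg <- integer(0); fg_gt <- integer(0)
    gpx <- NULL
    if (nrow(tgt)) {
      gpx <- yolo_to_pixels(tgt, input_size, input_size)
      G <- nrow(gpx)
      apx <- fl$acx * fl$stride; apy <- fl$acy * fl$stride
      iou <- box_iou_matrix(pmat, as.matrix(gpx[, c("x1", "y1", "x2", "y2")]))
      metric <- matrix(0, A, G)
      cand <- matrix(FALSE, A, G)
      for (g in seq_len(G)) {
        inside <- apx > gpx$x1[g] & apx < gpx$x2[g] &
                  apy > gpx$y1[g] & apy < gpx$y2[g]
        sc <- probs[, tgt$class_id[g] + 1L]
        mg <- (sc^tal_alpha) * (iou[, g]^tal_beta)
        mg[!inside] <- 0
        metric[, g] <- mg
        k <- min(tal_topk, sum(inside))
        if (k > 0) {
          top <- order(-mg)[seq_len(k)]
          cand[top[mg[top] > 0], g] <- TRUE
        }
      }
      # an anchor claimed by several targets keeps the highest-IoU one
      assign_gt <- rep(NA_integer_, A)
      multi <- which(rowSums(cand) > 0)
      for (a in multi) {
        gs <- which(cand[a, ])
        assign_gt[a] <- gs[which.max(iou[a, gs])]
      }
      fg <- which(!is.na(assign_gt))
      fg_gt <- assign_gt[fg]
      if (length(fg)) {
        # normalised target scores
        for (g in unique(fg_gt)) {
          sel <- fg[fg_gt == g]
          m_max <- max(metric[sel, g])
          i_max <- max(iou[sel, g])
          tscore[cbind(sel, tgt$class_id[g] + 1L)] <-
            metric[sel, g] * i_max / (m_max + 1e-9)
        }
      }
    }
    score_sum <- max(sum(tscore), 1)
    score_sum_total <- score_sum_total + score_sum
    fg_total <- fg_total + length(fg)

    # classification BCE (all anchors, all classes)
    eps <- 1e-12
    l_cls <- l_cls + sum(-(tscore * log(probs + eps) +
                           (1 - tscore) * log(1 - probs + eps))) / score_sum
    dcls <- (probs - tscore) / score_sum * gain_cls
    dbox_logits <- matrix(0, A, 4L * reg_max)

    if (length(fg)) {
      gm <- as.matrix(gpx[fg_gt, c("x1", "y1", "x2", "y2"), drop = FALSE])
      pm <- pmat[fg, , drop = FALSE]
      w_i <- tscore[cbind(fg, tgt$class_id[fg_gt] + 1L)] / score_sum
      cio <- ciou_vec(pm, gm)
      l_box <- l_box + sum(w_i * (1 - cio))
      dbox_px <- ciou_loss_grad(pm, gm, w_i) * gain_box
      # chain: pixels -> side expectations -> bin logits
      ddist <- cbind(-dbox_px[, 1L], -dbox_px[, 2L], dbox_px[, 3L], dbox_px[, 4L]) *
        fl$stride[fg]
      # DFL targets: edge distances in cell units, clamped to the bin range
      tl <- cbind(fl$acx[fg] - gm[, 1L] / fl$stride[fg],
                  fl$acy[fg] - gm[, 2L] / fl$stride[fg],
                  gm[, 3L] / fl$stride[fg] - fl$acx[fg],
                  gm[, 4L] / fl$stride[fg] - fl$acy[fg])
      tl <- pmin(pmax(tl, 0), reg_max - 1 - 0.01)
      lo <- floor(tl); hi <- lo + 1
      wl <- hi - tl; wh <- tl - lo
      for (side in 1:4) {
        p <- pside[[side]][fg, , drop = FALSE]
        d <- dexp[fg, side]
        # expectation gradient from the CIoU term
        gexp <- p * (matrix(bins, length(fg), reg_max, byrow = TRUE) - d) *
          ddist[, side]
        # distribution-focal cross-entropy on the two adjacent bins
        plo <- p[cbind(seq_along(fg), lo[, side] + 1L)]
        phi <- p[cbind(seq_along(fg), pmin(hi[, side], reg_max - 1) + 1L)]
        l_dfl <- l_dfl + sum(w_i * (-(wl[, side] * log(plo + eps) +
                                      wh[, side] * log(phi + eps)))) / 4
        tdist <- matrix(0, length(fg), reg_max)
        tdist[cbind(seq_along(fg), lo[, side] + 1L)] <- wl[, side]
        tdist[cbind(seq_along(fg), pmin(hi[, side], reg_max - 1) + 1L)] <-
          tdist[cbind(seq_along(fg), pmin(hi[, side], reg_max - 1) + 1L)] + wh[, side]
        gdfl <- (p - tdist) * (w_i * gain_dfl / 4)
        cols <- (side - 1L) * reg_max + seq_len(reg_max)
        dbox_logits[fg, cols] <- dbox_logits[fg, cols] + gexp + gdfl
      }
    }
    # scatter the flat gradients back into the per-level arrays
    at <- 0L
    for (l in seq_along(head)) {
      Al <- fl$sizes[l]
      dm <- dim(head[[l]]$cls)
      idx <- at + seq_len(Al)
      dhead[[l]]$cls[, , , n] <- array(dcls[idx, ], c(dm[1L], dm[2L], nc))
      dmb <- dim(head[[l]]$box)
      dhead[[l]]$box[, , , n] <- array(dbox_logits[idx, ],
                                       c(dmb[1L], dmb[2L], 4L * reg_max))
      at <- at + Al
    }
  }
  comp <- c(total = (gain_box * l_box + gain_cls * l_cls + gain_dfl * l_dfl),
            box = l_box, cls = l_cls, dfl = l_dfl)
  if (any(!is.finite(comp)))
    stop("non-finite loss component: ", paste(names(comp)[!is.finite(comp)],
                                              collapse = ", "))
  list(total = comp[["total"]], box = comp[["box"]], cls = comp[["cls"]],
       dfl = comp[["dfl"]], fg = fg_total, dhead = dhead)
}
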