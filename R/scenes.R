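# Synthetic lemon scenes.
#
# Emulates the statistics of orchard photographs of lemon trees: 1-6
# roughly elliptical fruit per image (two classes: healthy, and diseased
# fruit carrying dark lesion blobs), leaf-like occluders partially covering
# some fruit, and global illumination variation.  Ground-truth boxes bound
# the *visible* (un-occluded) extent of each fruit, and every rendered
# target has a label.  The generator is fully seeded: labels are identical
# across runs, and pixels too when rendering is on.

#' Describe a synthetic scene
#'
#' Defaults mirror the study conditions of the lemon dataset this generator
#' stands in for: 1-6 targets per image, a diseased-instance fraction of
#' about 14% (718 of 5159 instances), occlusion and lighting variation.
#'
#' @param width,height canvas size in pixels (640-3000 sensible).
#' @param n_targets fixed target count, or NULL to sample uniformly from 1-6.
#' @param frac_diseased probability a fruit is diseased (class 1).
#' @param occlusion_prob probability a fruit gets a leaf occluder.
#' @param illum_range global illumination gain range.
#' @param fruit_radius_frac fruit semi-major axis range, fraction of the
#'   shorter canvas edge.
#' @param lesion_count_range lesions per diseased fruit.
#' @param lesion_area_frac total lesion area as a fraction of fruit area.
#' @param seed integer seed.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(width = 1024L, height = 1024L, n_targets = NULL,
                       frac_diseased = 718 / 5159, occlusion_prob = 0.3,
                       illum_range = c(0.6, 1.3),
                       fruit_radius_frac = c(0.05, 0.16),
                       lesion_count_range = c(1L, 6L),
                       lesion_area_frac = c(0.05, 0.30), seed = 0L) {
  stopifnot(width >= 64, height >= 64,
            is.null(n_targets) || (n_targets >= 1 && n_targets <= 6),
            frac_diseased >= 0, frac_diseased <= 1,
            occlusion_prob >= 0, occlusion_prob <= 1,
            all(illum_range > 0), diff(illum_range) >= 0)
  sp <- list(width = as.integer(width), height = as.integer(height),
             n_targets = n_targets, frac_diseased = frac_diseased,
             occlusion_prob = occlusion_prob, illum_range = illum_range,
             fruit_radius_frac = fruit_radius_frac,
             lesion_count_range = as.integer(lesion_count_range),
             lesion_area_frac = lesion_area_frac, seed = as.integer(seed))
  class(sp) <- "scene_spec"
  sp
}

# ellipse membership over a pixel window; 0-based pixel centres at +0.5
ellipse_mask <- function(rows, cols, cx, cy, a, b, theta) {
  X <- outer(rep(1, length(rows)), cols - 0.5) - cx
  Y <- outer(rows - 0.5, rep(1, length(cols))) - cy
  u <- X * cos(theta) + Y * sin(theta)
  v <- -X * sin(theta) + Y * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

ellipse_window <- function(cx, cy, a, b, W, H) {
  r <- max(a, b)
  list(rows = max(1, floor(cy - r)):min(H, ceiling(cy + r + 1)),
       cols = max(1, floor(cx - r)):min(W, ceiling(cx + r + 1)))
}

#' Generate one synthetic scene
#'
#' @param spec a [scene_spec()].
#' @param render draw pixels (TRUE) or produce labels only (FALSE); labels
#'   are identical either way.
#' @return list with `image` ((H, W, 3) array in `[0, 1]`, or NULL),
#'   `labels` (a `labeled_image`), and `targets` (per-fruit metadata:
#'   geometry, class, visible fraction).
#' @export
generate_scene <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  with_local_seed(spec$seed, generate_scene_impl(spec, render))
}

generate_scene_impl <- function(spec, render) {
  W <- spec$width; H <- spec$height
  n <- if (is.null(spec$n_targets)) sample(1:6, 1L) else spec$n_targets
  rmin <- spec$fruit_radius_frac[1L] * min(W, H)
  rmax <- spec$fruit_radius_frac[2L] * min(W, H)

  fruits <- list()
  occluders <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(60L)) {
      a <- runif(1, rmin, rmax)
      b <- a * runif(1, 0.75, 1)
      theta <- runif(1, 0, pi)
      cx <- runif(1, a + 1, W - a - 1)
      cy <- runif(1, a + 1, H - a - 1)
      clash <- any(vapply(fruits, function(f)
        sqrt((f$cx - cx)^2 + (f$cy - cy)^2) < 1.05 * (max(f$a, f$b) + a),
        logical(1)))
      if (clash) next
      fr <- list(cx = cx, cy = cy, a = a, b = b, theta = theta,
                 diseased = runif(1) < spec$frac_diseased,
                 shade = runif(1, 0.9, 1.1),
                 hue = runif(1, -0.06, 0.06))
      occ <- NULL
      if (runif(1) < spec$occlusion_prob) {
        # leaf: elongated ellipse anchored near the fruit rim
        ang <- runif(1, 0, 2 * pi)
        la <- a * runif(1, 0.7, 1.3)
        lb <- la * runif(1, 0.35, 0.55)
        d <- max(a, b) * runif(1, 0.5, 0.95)
        occ <- list(cx = cx + d * cos(ang), cy = cy + d * sin(ang),
                    a = la, b = lb, theta = runif(1, 0, pi))
      }
      # visible fraction under this fruit's own occluder (cross-fruit
      # occlusion is prevented by the placement margin)
      vis <- 1
      if (!is.null(occ)) {
        win <- ellipse_window(fr$cx, fr$cy, fr$a, fr$b, W, H)
        fm <- ellipse_mask(win$rows, win$cols, fr$cx, fr$cy, fr$a, fr$b, fr$theta)
        om <- ellipse_mask(win$rows, win$cols, occ$cx, occ$cy, occ$a, occ$b, occ$theta)
        vis <- sum(fm & !om) / max(sum(fm), 1)
      }
      if (vis < 0.05) next   # > 95% occluded: resample the target
      fruits[[length(fruits) + 1L]] <- fr
      if (!is.null(occ)) occluders[[length(occluders) + 1L]] <- occ
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place target ", i, "; canvas too crowded")
  }

  # ground truth: bounding box of visible fruit pixels (half-open, 0-based)
  boxes <- list()
  targets <- list()
  for (i in seq_along(fruits)) {
    fr <- fruits[[i]]
    win <- ellipse_window(fr$cx, fr$cy, fr$a, fr$b, W, H)
    fm <- ellipse_mask(win$rows, win$cols, fr$cx, fr$cy, fr$a, fr$b, fr$theta)
    for (occ in occluders) {
      om <- ellipse_mask(win$rows, win$cols, occ$cx, occ$cy, occ$a, occ$b, occ$theta)
      fm <- fm & !om
    }
    vis_px <- which(fm, arr.ind = TRUE)
    if (!nrow(vis_px)) {
      # a neighbour's leaf buried this fruit: drop occluders over it until
      # some of it shows (keeps every rendered target labelled)
      for (oi in rev(seq_along(occluders))) {
        occ <- occluders[[oi]]
        om <- ellipse_mask(win$rows, win$cols, occ$cx, occ$cy, occ$a, occ$b, occ$theta)
        fm0 <- ellipse_mask(win$rows, win$cols, fr$cx, fr$cy, fr$a, fr$b, fr$theta)
        if (any(fm0 & om)) {
          occluders[[oi]] <- NULL
          fm <- fm0
          for (o2 in occluders) {
            om2 <- ellipse_mask(win$rows, win$cols, o2$cx, o2$cy, o2$a, o2$b, o2$theta)
            fm <- fm & !om2
          }
          if (any(fm)) break
        }
      }
      vis_px <- which(fm, arr.ind = TRUE)
      if (!nrow(vis_px)) stop("fully occluded target survived resampling")
    }
    rows0 <- win$rows[vis_px[, 1L]] - 1L   # 0-based
    cols0 <- win$cols[vis_px[, 2L]] - 1L
    boxes[[i]] <- data.frame(class_id = as.integer(fr$diseased),
                             x1 = min(cols0), y1 = min(rows0),
                             x2 = max(cols0) + 1L, y2 = max(rows0) + 1L)
    targets[[i]] <- c(fr, list(visible_frac = sum(fm) / max(sum(
      ellipse_mask(win$rows, win$cols, fr$cx, fr$cy, fr$a, fr$b, fr$theta)), 1)))
  }
  px <- do.call(rbind, boxes)
  labels <- labeled_image(W, H, pixels_to_yolo(px, W, H))

  img <- NULL
  if (render) {
    gain <- runif(1, spec$illum_range[1L], spec$illum_range[2L])
    img <- render_scene(spec, fruits, occluders, gain)
  }
  list(image = img, labels = labels, targets = targets)
}

render_scene <- function(spec, fruits, occluders, gain) {
  W <- spec$width; H <- spec$height
  # foliage background: green base + a few broad radial gradients
  base <- c(0.18, 0.34, 0.11)
  img <- array(rep(base, each = H * W), c(H, W, 3L))
  xs <- (seq_len(W) - 0.5) / W
  ys <- (seq_len(H) - 0.5) / H
  for (k in 1:3) {
    gx <- runif(1); gy <- runif(1); amp <- runif(1, -0.06, 0.06)
    field <- amp * exp(-(outer((ys - gy)^2, (xs - gx)^2, "+")) / 0.18)
    for (ci in 1:3) img[, , ci] <- img[, , ci] + field * c(0.6, 1, 0.4)[ci]
  }
  for (fr in fruits) {
    win <- ellipse_window(fr$cx, fr$cy, fr$a, fr$b, W, H)
    fm <- ellipse_mask(win$rows, win$cols, fr$cx, fr$cy, fr$a, fr$b, fr$theta)
    X <- outer(rep(1, length(win$rows)), win$cols - 0.5) - fr$cx
    Y <- outer(win$rows - 0.5, rep(1, length(win$cols))) - fr$cy
    u <- X * cos(fr$theta) + Y * sin(fr$theta)
    v <- -X * sin(fr$theta) + Y * cos(fr$theta)
    d2 <- (u / fr$a)^2 + (v / fr$b)^2
    shade <- (1 - 0.35 * d2) * fr$shade
    col <- c(0.86 + fr$hue, 0.72, 0.16)
    for (ci in 1:3) {
      ch <- img[win$rows, win$cols, ci]
      val <- col[ci] * shade
      ch[fm] <- val[fm]
      img[win$rows, win$cols, ci] <- ch
    }
    if (fr$diseased) {
      k <- sample(spec$lesion_count_range[1L]:spec$lesion_count_range[2L], 1L)
      area_frac <- runif(1, spec$lesion_area_frac[1L], spec$lesion_area_frac[2L])
      lr <- sqrt(area_frac * fr$a * fr$b / k)    # per-lesion radius
      for (j in seq_len(k)) {
        phi <- runif(1, 0, 2 * pi)
        rho <- runif(1, 0, 0.6)
        lx <- fr$cx + rho * fr$a * cos(phi)
        ly <- fr$cy + rho * fr$b * sin(phi)
        lm <- ellipse_mask(win$rows, win$cols, lx, ly, lr * runif(1, 0.8, 1.2),
                           lr * runif(1, 0.6, 1), runif(1, 0, pi)) & fm
        lcol <- c(0.30, 0.17, 0.05)
        for (ci in 1:3) {
          ch <- img[win$rows, win$cols, ci]
          val <- lcol[ci] * shade
          ch[lm] <- val[lm]
          img[win$rows, win$cols, ci] <- ch
        }
      }
    }
  }
  for (occ in occluders) {
    win <- ellipse_window(occ$cx, occ$cy, occ$a, occ$b, W, H)
    if (!length(win$rows) || !length(win$cols)) next
    om <- ellipse_mask(win$rows, win$cols, occ$cx, occ$cy, occ$a, occ$b, occ$theta)
    lcol <- c(0.10, 0.27, 0.08) * runif(1, 0.85, 1.15)
    for (ci in 1:3) {
      ch <- img[win$rows, win$cols, ci]
      ch[om] <- lcol[ci]
      img[win$rows, win$cols, ci] <- ch
    }
  }
  noise <- array(runif(H * W, -0.02, 0.02), c(H, W))
  for (ci in 1:3) img[, , ci] <- img[, , ci] + noise
  pmin(pmax(img * gain, 0), 1)
}

#' Generate a synthetic detection dataset on disk
#'
#' Writes `scene_####.png` / `scene_####.txt` pairs and a `manifest.yaml`
#' usable by the data input/output and training layers.  Image i is produced
#' with seed `spec$seed + i`, so label files are byte-identical across runs.
#'
#' @param n_images number of scenes.
#' @param spec a [scene_spec()]; its seed acts as the dataset base seed.
#' @param out_dir output directory; must be empty or absent unless
#'   `overwrite`.
#' @param overwrite allow writing into a non-empty directory.
#' @return the manifest (invisibly written to `out_dir/manifest.yaml`).
#' @export
generate_dataset <- function(n_images, spec, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("output directory ", out_dir, " is not empty (use overwrite = TRUE)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_images)) {
    sp <- spec
    sp$seed <- spec$seed + i
    sc <- generate_scene(sp)
    stem <- sprintf("scene_%04d", i)
    png::writePNG(sc$image, file.path(out_dir, paste0(stem, ".png")))
    write_yolo_labels(sc$labels, file.path(out_dir, paste0(stem, ".txt")))
  }
  manifest <- list(train = out_dir, val = out_dir,
                   names = list(`0` = "lemon", `1` = "disease"))
  write_manifest(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Label / render consistency check
#'
#' Re-detects fruit by an illumination-invariant colour mask (fruit pixels
#' are the only yellow-dominant ones), labels connected components, and
#' checks that each ground-truth box is recovered with IoU at least `iou`.
#' Used as the generator's self-check oracle.
#'
#' @param image rendered scene, (H, W, 3).
#' @param labels the scene's `labeled_image`.
#' @param iou required overlap (0.8).
#' @return logical vector: each ground-truth box recovered.
#' @export
scene_selfcheck <- function(image, labels, iou = 0.8) {
  mask <- image[, , 1L] > 0.8 * image[, , 2L] & image[, , 1L] > 1.8 * image[, , 3L]
  lab <- t(EBImage::bwlabel(t(mask)))          # EBImage works in (x, y)
  px <- yolo_to_pixels(labels$boxes, labels$width, labels$height)
  vapply(seq_len(nrow(px)), function(i) {
    g <- c(px$x1[i], px$y1[i], px$x2[i], px$y2[i])
    # components whose pixels fall mostly inside the (slightly grown) box
    gw <- g + c(-1, -1, 1, 1) * 0.15 * c(g[3] - g[1], g[4] - g[2],
                                         g[3] - g[1], g[4] - g[2])
    ids <- unique(lab[lab > 0])
    sel <- integer(0)
    for (id in ids) {
      pxl <- which(lab == id, arr.ind = TRUE)
      cols <- pxl[, 2L] - 1L; rows <- pxl[, 1L] - 1L
      inside <- mean(cols >= gw[1] & cols < gw[3] & rows >= gw[2] & rows < gw[4])
      if (inside > 0.5) sel <- c(sel, id)
    }
    if (!length(sel)) return(FALSE)
    pxl <- which(matrix(lab %in% sel, nrow(lab)), arr.ind = TRUE)
    b <- c(min(pxl[, 2L]) - 1L, min(pxl[, 1L]) - 1L,
           max(pxl[, 2L]), max(pxl[, 1L]))
    iw <- max(0, min(b[3], g[3]) - max(b[1], g[1]))
    ih <- max(0, min(b[4], g[4]) - max(b[2], g[2]))
    inter <- iw * ih
    un <- (b[3] - b[1]) * (b[4] - b[2]) + (g[3] - g[1]) * (g[4] - g[2]) - inter
    inter / un >= iou
  }, logical(1))
}
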