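# Target-centred tiling: crop fixed-size windows around annotated targets
# from high-resolution images and regenerate normalised labels in window
# coordinates, preserving (and flagging) boxes clipped by a window edge.

#' Tile a labelled image into target-centred crops
#'
#' Each window is centred on a target centroid and clamped to the image
#' bounds; a new window is only opened for a target not already fully
#' contained in a chosen window, so co-occurring targets share tiles.  Every
#' source box whose visible fraction inside a window is at least
#' `min_visibility` is written into that window's labels, clipped to the
#' window and flagged when clipping occurred.  Images smaller than the tile
#' size in either dimension pass through as a single untiled record.
#'
#' @param src a `labeled_image` (see [read_yolo_labels()]).
#' @param image optional (H, W, 3) array; when given, each record carries the
#'   cropped pixels.
#' @param tile window edge in pixels (1024).
#' @param min_visibility minimum visible-area fraction for keeping a clipped
#'   box (default 0.3).
#' @return list of `tile_record` objects: `source`, `x_off`, `y_off`,
#'   `width`, `height`, `boxes` (normalised to the tile), `edge_flags`.
#' @export
tile_image <- function(src, image = NULL, tile = 1024L, min_visibility = 0.3) {
  stopifnot(inherits(src, "labeled_image"))
  W <- src$width; H <- src$height
  px <- yolo_to_pixels(src$boxes, W, H)
  if (W < tile || H < tile) {
    rec <- tile_record(src, 0L, 0L, W, H, px, image, min_visibility)
    return(list(rec))
  }
  origins <- matrix(numeric(0), 0L, 2L)
  for (i in seq_len(nrow(px))) {
    if (nrow(origins)) {
      inside <- px$x1[i] >= origins[, 1L] & px$x2[i] <= origins[, 1L] + tile &
                px$y1[i] >= origins[, 2L] & px$y2[i] <= origins[, 2L] + tile
      if (any(inside)) next
    }
    cx <- (px$x1[i] + px$x2[i]) / 2
    cy <- (px$y1[i] + px$y2[i]) / 2
    ox <- min(max(round(cx - tile / 2), 0), W - tile)
    oy <- min(max(round(cy - tile / 2), 0), H - tile)
    origins <- rbind(origins, c(ox, oy))
  }
  if (!nrow(origins)) origins <- matrix(c(0, 0), 1L, 2L)  # background image
  lapply(seq_len(nrow(origins)), function(j)
    tile_record(src, origins[j, 1L], origins[j, 2L], tile, tile, px,
                image, min_visibility))
}

tile_record <- function(src, x_off, y_off, w, h, px, image, min_visibility) {
  keep <- integer(0); flags <- logical(0)
  boxes <- empty_boxes()
  if (nrow(px)) {
    ix1 <- pmax(px$x1, x_off); ix2 <- pmin(px$x2, x_off + w)
    iy1 <- pmax(px$y1, y_off); iy2 <- pmin(px$y2, y_off + h)
    vis <- pmax(0, ix2 - ix1) * pmax(0, iy2 - iy1) /
           ((px$x2 - px$x1) * (px$y2 - px$y1))
    keep <- which(vis >= min_visibility)
    if (length(keep)) {
      clipped <- data.frame(class_id = px$class_id[keep],
                            x1 = ix1[keep] - x_off, y1 = iy1[keep] - y_off,
                            x2 = ix2[keep] - x_off, y2 = iy2[keep] - y_off)
      flags <- vis[keep] < 1
      boxes <- pixels_to_yolo(clipped, w, h)
    }
  }
  rec <- list(source = src$path, x_off = as.integer(x_off),
              y_off = as.integer(y_off), width = as.integer(w),
              height = as.integer(h), boxes = boxes, edge_flags = flags)
  if (!is.null(image))
    rec$image <- image[y_off + seq_len(h), x_off + seq_len(w), , drop = FALSE]
  class(rec) <- "tile_record"
  rec
}

#' Write tile records to a dataset directory
#'
#' Writes per-tile YOLO label files, a JSON sidecar with the tiling metadata
#' (`source`, `x_off`, `y_off`, `edge_flags`), and the cropped PNG when the
#' record carries pixels.
#'
#' @param tiles list of `tile_record`s.
#' @param dir output directory (created if needed).
#' @param stem filename stem; tiles are numbered `<stem>_t01`, ...
#' @return character vector of label file paths.
#' @export
write_tiles <- function(tiles, dir, stem) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(length(tiles))
  for (j in seq_along(tiles)) {
    rec <- tiles[[j]]
    base <- file.path(dir, sprintf("%s_t%02d", stem, j))
    write_yolo_labels(rec$boxes, paste0(base, ".txt"))
    jsonlite::write_json(
      list(source = rec$source, x_off = rec$x_off, y_off = rec$y_off,
           width = rec$width, height = rec$height,
           edge_flags = rec$edge_flags),
      paste0(base, ".json"), auto_unbox = TRUE)
    if (!is.null(rec$image))
      png::writePNG(rec$image, paste0(base, ".png"))
    out[j] <- paste0(base, ".txt")
  }
  invisible(out)
}
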