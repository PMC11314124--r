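# YOLO-format label input/output and dataset manifests.
#
# A label file holds one line per box: `class cx cy w h`, whitespace
# separated, centre/size normalised to [0, 1].  Pixel boxes are half-open
# [x1, x2) x [y1, y2) in 0-based image coordinates, so a box spanning pixel
# columns 10..19 has x1 = 10, x2 = 20.

#' Read YOLO-format labels
#'
#' @param path label file (`<image_stem>.txt`).  A missing file yields an
#'   empty box list with a warning, matching the convention that un-annotated
#'   images are background-only.
#' @param image_size `c(width, height)` of the image the labels refer to.
#' @return object of class `labeled_image`: list with `width`, `height` and
#'   `boxes` (data.frame `class_id`, `cx`, `cy`, `w`, `h`, normalised).
#' @export
read_yolo_labels <- function(path, image_size) {
  stopifnot(length(image_size) == 2L)
  if (!file.exists(path)) {
    warning("label file not found: ", path, " (treating as zero boxes)")
    return(labeled_image(image_size[1L], image_size[2L], empty_boxes()))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(labeled_image(image_size[1L], image_size[2L], empty_boxes()))
  parts <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  bad_len <- which(vapply(parts, length, integer(1)) != 5L)
  if (length(bad_len))
    stop("malformed label line(s) ", paste(bad_len, collapse = ", "), " in ", path)
  m <- do.call(rbind, parts)
  boxes <- data.frame(class_id = as.integer(m[, 1L]), cx = m[, 2L], cy = m[, 3L],
                      w = m[, 4L], h = m[, 5L])
  bad <- which(boxes$cx - boxes$w / 2 < -1e-9 | boxes$cx + boxes$w / 2 > 1 + 1e-9 |
               boxes$cy - boxes$h / 2 < -1e-9 | boxes$cy + boxes$h / 2 > 1 + 1e-9 |
               boxes$w <= 0 | boxes$h <= 0 | boxes$class_id < 0)
  if (length(bad))
    stop("out-of-range coordinates on line(s) ", paste(bad, collapse = ", "),
         " in ", path)
  labeled_image(image_size[1L], image_size[2L], boxes)
}

labeled_image <- function(width, height, boxes, path = NA_character_) {
  x <- list(path = path, width = as.integer(width), height = as.integer(height),
            boxes = boxes)
  class(x) <- "labeled_image"
  x
}

empty_boxes <- function() {
  data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
             w = numeric(0), h = numeric(0))
}

#' Write YOLO-format labels
#'
#' Round-trips with [read_yolo_labels()] to 6 decimal places.
#'
#' @param labels a `labeled_image` (or a bare box data.frame).
#' @param path output file.
#' @export
write_yolo_labels <- function(labels, path) {
  boxes <- if (inherits(labels, "labeled_image")) labels$boxes else labels
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", boxes$class_id, boxes$cx,
                   boxes$cy, boxes$w, boxes$h)
  writeLines(lines, path)
  invisible(path)
}

#' Convert normalised YOLO boxes to pixel corners (and back)
#'
#' @param boxes data.frame with `cx`, `cy`, `w`, `h` in [0, 1].
#' @param width,height image size in pixels.
#' @return `yolo_to_pixels`: data.frame with `class_id`, `x1`, `y1`, `x2`,
#'   `y2` (half-open pixel corners); `pixels_to_yolo`: the reverse.
#' @export
yolo_to_pixels <- function(boxes, width, height) {
  data.frame(class_id = boxes$class_id,
             x1 = (boxes$cx - boxes$w / 2) * width,
             y1 = (boxes$cy - boxes$h / 2) * height,
             x2 = (boxes$cx + boxes$w / 2) * width,
             y2 = (boxes$cy + boxes$h / 2) * height)
}

#' @rdname yolo_to_pixels
#' @export
pixels_to_yolo <- function(boxes, width, height) {
  data.frame(class_id = boxes$class_id,
             cx = (boxes$x1 + boxes$x2) / 2 / width,
             cy = (boxes$y1 + boxes$y2) / 2 / height,
             w = (boxes$x2 - boxes$x1) / width,
             h = (boxes$y2 - boxes$y1) / height)
}

#' Dataset manifest input/output
#'
#' The manifest is a YAML file with `train`/`val` directories and a `names`
#' map (`0: lemon`, `1: disease`).
#'
#' @param path YAML file path.
#' @param manifest list with `train`, `val`, `names`.
#' @export
read_manifest <- function(path) yaml::read_yaml(path)

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}
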