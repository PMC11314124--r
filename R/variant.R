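# Model variants: the 8 ablation architectures arise from three flags
# (use_sac, use_sod, use_cbam) over the nano-scale baseline.

#' Describe a detector variant
#'
#' A declarative description of one member of the model family.  The baseline
#' (all flags off) is the standard nano-scale anchor-free detector; enabling
#' all three flags yields the full lemon-surface-disease model.
#'
#' @param use_sac replace backbone C2f blocks with C2f-SAC and insert a
#'   standalone SAC convolution (switchable atrous convolution) after the
#'   stride-4 downsample.
#' @param use_sod add the stride-4 (P2) fusion path and a fourth detection
#'   head for small objects.
#' @param use_cbam insert CBAM attention blocks at the documented sites.
#' @param num_classes number of object classes (2: healthy lemon / diseased).
#' @param depth_multiple,width_multiple,max_channels scale multipliers; the
#'   nano scale is 0.33 / 0.25 / 1024.
#' @param input_size square input edge in pixels; must be divisible by 32
#'   (by 64 when `use_sod`, so the stride-4 grid is integral).
#' @param sac_rate atrous rate r of the SAC dilated branch (integer >= 2).
#' @param sac_placement,cbam_placement character vectors naming the insertion
#'   sites; the defaults are the placements whose parameter budgets match the
#'   published architecture (see the model YAML written by
#'   [write_variant()]).
#' @return an object of class `lsd_variant`.
#' @export
model_variant <- function(use_sac = FALSE, use_sod = FALSE, use_cbam = FALSE,
                          num_classes = 2, depth_multiple = 0.33,
                          width_multiple = 0.25, max_channels = 1024,
                          input_size = 640, sac_rate = 3,
                          sac_placement = c("backbone_saconv_p2",
                                            "c2f_sac_stage1", "c2f_sac_stage3"),
                          cbam_placement = c("p3_tap", "p4_tap", "p5_sppf",
                                             "td_cat1", "td_cat2")) {
  if (!is.numeric(num_classes) || num_classes < 1)
    stop("num_classes must be >= 1")
  if (depth_multiple <= 0 || width_multiple <= 0 || max_channels < 64)
    stop("invalid scale multipliers")
  stride_req <- if (isTRUE(use_sod)) 64L else 32L
  if (input_size %% stride_req != 0)
    stop("input_size must be divisible by ", stride_req,
         if (isTRUE(use_sod)) " when use_sod is enabled" else "")
  if (sac_rate < 2) stop("sac_rate must be an integer >= 2")
  v <- list(use_sac = isTRUE(use_sac), use_sod = isTRUE(use_sod),
            use_cbam = isTRUE(use_cbam), num_classes = as.integer(num_classes),
            depth_multiple = depth_multiple, width_multiple = width_multiple,
            max_channels = as.integer(max_channels),
            input_size = as.integer(input_size), sac_rate = as.integer(sac_rate),
            sac_placement = sac_placement, cbam_placement = cbam_placement)
  class(v) <- "lsd_variant"
  v
}

#' All eight ablation variants
#'
#' @param ... passed to [model_variant()] (e.g. `num_classes`).
#' @return a named list of 8 `lsd_variant` objects, from `baseline`
#'   (no flags) to `sac_sod_cbam` (the full model).
#' @export
variant_grid <- function(...) {
  grid <- expand.grid(sac = c(FALSE, TRUE), sod = c(FALSE, TRUE),
                      cbam = c(FALSE, TRUE))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    nm <- paste(c(if (grid$sac[i]) "sac", if (grid$sod[i]) "sod",
                  if (grid$cbam[i]) "cbam"), collapse = "_")
    if (nm == "") nm <- "baseline"
    out[[nm]] <- model_variant(use_sac = grid$sac[i], use_sod = grid$sod[i],
                               use_cbam = grid$cbam[i], ...)
  }
  out
}

#' @export
print.lsd_variant <- function(x, ...) {
  cat(sprintf("<lsd_variant> sac=%s sod=%s cbam=%s nc=%d depth=%.2f width=%.2f input=%d\n",
              x$use_sac, x$use_sod, x$use_cbam, x$num_classes,
              x$depth_multiple, x$width_multiple, x$input_size))
  invisible(x)
}

#' Write / read a variant config as YAML
#'
#' The YAML carries all [model_variant()] fields, including the documented
#' SAC / CBAM insertion-point lists.
#'
#' @param variant an `lsd_variant`.
#' @param path file path.
#' @return `read_variant()` returns an `lsd_variant`.
#' @export
write_variant <- function(variant, path) {
  stopifnot(inherits(variant, "lsd_variant"))
  yaml::write_yaml(unclass(variant), path)
  invisible(path)
}

#' @rdname write_variant
#' @export
read_variant <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(model_variant, raw[intersect(names(raw), names(formals(model_variant)))])
}

# width scaling: cap at max_channels, scale, round to a multiple of 8
scaled_width <- function(c, wm, max_ch) {
  c <- min(c, max_ch)
  max(8L, as.integer(round(c * wm / 8) * 8))
}

scaled_depth <- function(n, dm) max(1L, as.integer(round(n * dm)))

variant_widths <- function(v) {
  vapply(c(64, 128, 256, 512, 1024), scaled_width,
         integer(1), wm = v$width_multiple, max_ch = v$max_channels)
}
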