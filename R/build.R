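# Model assembly: a flat DAG of modules wired by node names, executed in
# order for the forward pass and in reverse for backpropagation.

add_node <- function(g, name, module, from) {
  g$nodes[[name]] <- list(name = name, module = module, from = from)
  g$last <- name
  g
}

#' Build a detector network from a variant description
#'
#' Assembles the nano-scale backbone (stem + four conv/C2f stages + SPPF), the
#' FPN+PAN neck and the decoupled anchor-free head, inserting C2f-SAC blocks
#' and a standalone SAC convolution when `use_sac`, CBAM blocks at the
#' documented sites when `use_cbam`, and the stride-4 fusion path plus fourth
#' head when `use_sod`.
#'
#' @param variant an [model_variant()] object.
#' @param seed integer seed for weight initialisation (default 0).
#' @return an object of class `lsd_model`.
#' @export
build_model <- function(variant, seed = 0) {
  stopifnot(inherits(variant, "lsd_variant"))
  set.seed(seed)
  w <- variant_widths(variant)     # c(16, 32, 64, 128, 256) at nano
  dm <- variant$depth_multiple
  n_deep <- scaled_depth(6, dm)    # stages 2-3
  n_shallow <- scaled_depth(3, dm) # stages 1, 4 and neck
  nc <- variant$num_classes
  r <- variant$sac_rate
  sac_on <- function(site) variant$use_sac && site %in% variant$sac_placement
  cbam_on <- function(site) variant$use_cbam && site %in% variant$cbam_placement

  g <- new.env()
  g$nodes <- list()

  ## backbone
  stem <- mk_convblock(3, w[1], 3, 2)
  stem$is_input_layer <- TRUE   # no image gradient needed
  g <- add_node(g, "stem", stem, "input")
  g <- add_node(g, "down1", mk_convblock(w[1], w[2], 3, 2), "stem")
  if (sac_on("backbone_saconv_p2"))
    g <- add_node(g, "saconv_p2", mk_sac(w[2], w[2], 3, r, ctx = TRUE), g$last)
  g <- add_node(g, "stage1",
                if (sac_on("c2f_sac_stage1"))
                  build_c2f_sac(w[2], w[2], n_shallow, TRUE, r)
                else mk_c2f(w[2], w[2], n_shallow, TRUE), g$last)
  p2_tap <- g$last
  g <- add_node(g, "down2", mk_convblock(w[2], w[3], 3, 2), g$last)
  g <- add_node(g, "stage2",
                if (sac_on("c2f_sac_stage2"))
                  build_c2f_sac(w[3], w[3], n_deep, TRUE, r)
                else mk_c2f(w[3], w[3], n_deep, TRUE), g$last)
  if (cbam_on("p3_tap")) g <- add_node(g, "cbam_p3", mk_cbam(w[3]), g$last)
  p3_tap <- g$last
  g <- add_node(g, "down3", mk_convblock(w[3], w[4], 3, 2), g$last)
  g <- add_node(g, "stage3",
                if (sac_on("c2f_sac_stage3"))
                  build_c2f_sac(w[4], w[4], n_deep, TRUE, r)
                else mk_c2f(w[4], w[4], n_deep, TRUE), g$last)
  if (cbam_on("p4_tap")) g <- add_node(g, "cbam_p4", mk_cbam(w[4]), g$last)
  p4_tap <- g$last
  g <- add_node(g, "down4", mk_convblock(w[4], w[5], 3, 2), g$last)
  g <- add_node(g, "stage4",
                if (sac_on("c2f_sac_stage4"))
                  build_c2f_sac(w[5], w[5], n_shallow, TRUE, r)
                else mk_c2f(w[5], w[5], n_shallow, TRUE), g$last)
  g <- add_node(g, "sppf", mk_sppf(w[5], w[5]), g$last)
  if (cbam_on("p5_sppf")) g <- add_node(g, "cbam_p5", mk_cbam(w[5]), g$last)
  p5_tap <- g$last

  ## top-down path
  g <- add_node(g, "td_up1", mk_upsample2(), p5_tap)
  g <- add_node(g, "td_cat1", mk_concat(), c("td_up1", p4_tap))
  if (cbam_on("td_cat1")) g <- add_node(g, "cbam_td1", mk_cbam(w[5] + w[4]), g$last)
  g <- add_node(g, "td_p4", mk_c2f(w[5] + w[4], w[4], n_shallow, FALSE), g$last)
  g <- add_node(g, "td_up2", mk_upsample2(), "td_p4")
  g <- add_node(g, "td_cat2", mk_concat(), c("td_up2", p3_tap))
  if (cbam_on("td_cat2")) g <- add_node(g, "cbam_td2", mk_cbam(w[4] + w[3]), g$last)
  g <- add_node(g, "td_p3", mk_c2f(w[4] + w[3], w[3], n_shallow, FALSE), g$last)

  if (variant$use_sod) {
    ## extend top-down to stride 4, then return bottom-up through all levels
    g <- add_node(g, "td_up3", mk_upsample2(), "td_p3")
    g <- add_node(g, "td_cat3", mk_concat(), c("td_up3", p2_tap))
    g <- add_node(g, "head_p2", mk_c2f(w[3] + w[2], w[2], n_shallow, FALSE), g$last)
    g <- add_node(g, "bu_down2", mk_convblock(w[2], w[2], 3, 2), "head_p2")
    g <- add_node(g, "bu_cat3", mk_concat(), c("bu_down2", "td_p3"))
    g <- add_node(g, "head_p3", mk_c2f(w[2] + w[3], w[3], n_shallow, FALSE), g$last)
    g <- add_node(g, "bu_down3", mk_convblock(w[3], w[3], 3, 2), "head_p3")
    g <- add_node(g, "bu_cat4", mk_concat(), c("bu_down3", "td_p4"))
    g <- add_node(g, "head_p4", mk_c2f(w[3] + w[4], w[4], n_shallow, FALSE), g$last)
    g <- add_node(g, "bu_down4", mk_convblock(w[4], w[4], 3, 2), "head_p4")
    g <- add_node(g, "bu_cat5", mk_concat(), c("bu_down4", p5_tap))
    g <- add_node(g, "head_p5", mk_c2f(w[4] + w[5], w[5], n_shallow, FALSE), g$last)
    heads <- c("head_p2", "head_p3", "head_p4", "head_p5")
    strides <- c(4L, 8L, 16L, 32L)
    head_ch <- c(w[2], w[3], w[4], w[5])
    levels <- c("P2", "P3", "P4", "P5")
  } else {
    g <- add_node(g, "bu_down3", mk_convblock(w[3], w[3], 3, 2), "td_p3")
    g <- add_node(g, "bu_cat3", mk_concat(), c("bu_down3", "td_p4"))
    g <- add_node(g, "head_p4", mk_c2f(w[3] + w[4], w[4], n_shallow, FALSE), g$last)
    g <- add_node(g, "bu_down4", mk_convblock(w[4], w[4], 3, 2), "head_p4")
    g <- add_node(g, "bu_cat5", mk_concat(), c("bu_down4", p5_tap))
    g <- add_node(g, "head_p5", mk_c2f(w[4] + w[5], w[5], n_shallow, FALSE), g$last)
    heads <- c("td_p3", "head_p4", "head_p5")
    strides <- c(8L, 16L, 32L)
    head_ch <- c(w[3], w[4], w[5])
    levels <- c("P3", "P4", "P5")
  }
  g <- add_node(g, "detect", mk_detect(nc, head_ch), heads)

  model <- list(nodes = g$nodes, variant = variant, strides = strides,
                head_nodes = heads, levels = levels, head_ch = head_ch,
                reg_max = 16L, seed = seed)
  class(model) <- "lsd_model"
  init_head_biases(model)
  model
}

# conventional head bias priors: box branch bias 1, class branch bias set so
# initial foreground probability is low and roughly scale-matched
init_head_biases <- function(model) {
  det <- model$nodes$detect$module
  nc <- det$nc
  for (l in seq_len(det$nl)) {
    s <- model$strides[l]
    det$children[[paste0("box", l, "c")]]$params$b[] <- 1.0
    det$children[[paste0("cls", l, "c")]]$params$b[] <-
      log(5 / nc / (model$variant$input_size / s)^2)
  }
  invisible(model)
}

#' @export
print.lsd_model <- function(x, ...) {
  np <- count_parameters(x)
  cat(sprintf("<lsd_model> %d nodes, heads: %s, %s trainable parameters (%.2f M)\n",
              length(x$nodes), paste(x$levels, collapse = "/"),
              format(np, big.mark = ","), np / 1e6))
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact number of trainable scalar weights of a network (or single module):
#' convolution kernels, SAC weight offsets and switches, attention MLPs and
#' batch-norm affine terms.  Batch-norm running statistics are buffers, not
#' parameters, and are excluded.  The count is deterministic for a fixed
#' variant and invariant to input size and batch size.
#'
#' @param network an `lsd_model` or a single module.
#' @return integer-valued count.
#' @export
count_parameters <- function(network) {
  if (inherits(network, "lsd_module")) return(module_n_params(network))
  stopifnot(inherits(network, "lsd_model"))
  sum(vapply(network$nodes, function(n) module_n_params(n$module), numeric(1)))
}

# run the graph; returns an environment of node outputs
forward_graph <- function(model, x, train = FALSE) {
  outs <- new.env(parent = emptyenv())
  for (node in model$nodes) {
    ins <- lapply(node$from, function(f) if (f == "input") x else get(f, outs))
    y <- if (length(ins) == 1L && !identical(node$module$type, "detect"))
      m_fwd(node$module, ins[[1L]], train)
    else m_fwd(node$module, ins, train)
    assign(node$name, y, outs)
  }
  outs
}

# backpropagate from the head gradients (list per level of $box/$cls arrays)
backward_graph <- function(model, outs, dhead) {
  acc <- new.env(parent = emptyenv())
  assign("detect", dhead, acc)
  for (node in rev(model$nodes)) {
    if (!exists(node$name, acc, inherits = FALSE)) next
    dout <- get(node$name, acc)
    din <- m_bwd(node$module, dout)
    if (length(node$from) == 1L && node$from != "input") din <- list(din)
    for (i in seq_along(node$from)) {
      f <- node$from[i]
      if (f == "input") next
      prev <- if (exists(f, acc, inherits = FALSE)) get(f, acc) else 0
      assign(f, prev + din[[i]], acc)
    }
  }
  invisible(acc)
}

#' Run the backbone and neck, returning the multi-scale feature maps
#'
#' @param network an `lsd_model`.
#' @param image_batch array (H, W, 3, N) with H, W divisible by the network's
#'   maximum stride (32).
#' @return named list of feature arrays, one per active head level
#'   (`P3`,`P4`,`P5`, plus `P2` when the variant has the small-object head);
#'   at 640x640 input the spatial sizes are 160/80/40/20.
#' @export
forward_features <- function(network, image_batch) {
  stopifnot(inherits(network, "lsd_model"))
  d <- dim(image_batch)
  if (length(d) != 4L || d[3L] != 3L)
    stop("image_batch must be (H, W, 3, N)")
  ms <- max(network$strides)
  if (d[1L] %% ms != 0 || d[2L] %% ms != 0)
    stop("input size must be divisible by the maximum stride (", ms, ")")
  outs <- forward_graph(network, image_batch, train = FALSE)
  setNames(lapply(network$head_nodes, function(h) get(h, outs)), network$levels)
}

# full forward returning raw head outputs (list per level of $box/$cls)
forward_heads <- function(model, x, train = FALSE) {
  outs <- forward_graph(model, x, train)
  list(outs = outs, head = get("detect", outs))
}
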