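# Seeded training loop: AdamW with decoupled weight decay, linear
# learning-rate decay, optional horizontal-flip augmentation, loss history
# and checkpointing.

#' Training configuration
#'
#' Defaults are the training hyperparameters of the detection protocol:
#' AdamW with initial learning rate 0.001667, momentum (beta1) 0.9, weight
#' decay 0.0005, batch size 8, 200 epochs at 640x640 input.  The learning
#' rate decays linearly to `lrf * lr0` over the run.
#'
#' @param lr0 initial learning rate.
#' @param momentum AdamW beta1.
#' @param beta2 AdamW beta2.
#' @param weight_decay decoupled weight decay (applied to convolution and
#'   MLP weight matrices only, not to norms or biases).
#' @param batch_size images per optimizer step.
#' @param epochs passes over the dataset (when `iterations` is not given to
#'   [fit()]).
#' @param input_size square input edge.
#' @param lrf final learning-rate fraction.
#' @param flip_augment random horizontal flips (off by default).
#' @param seed RNG seed for shuffling and augmentation.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr0 = 0.001667, momentum = 0.9, beta2 = 0.999,
                         weight_decay = 0.0005, batch_size = 8L, epochs = 200L,
                         input_size = 640L, lrf = 0.01, flip_augment = FALSE,
                         seed = 0L) {
  stopifnot(lr0 > 0, momentum > 0, momentum < 1, weight_decay >= 0,
            batch_size >= 1, epochs >= 1, input_size %% 32 == 0)
  cfg <- list(lr0 = lr0, momentum = momentum, beta2 = beta2,
              weight_decay = weight_decay, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), input_size = as.integer(input_size),
              lrf = lrf, flip_augment = isTRUE(flip_augment),
              seed = as.integer(seed))
  class(cfg) <- "train_config"
  cfg
}

adamw_init <- function(model) {
  handles <- unlist(lapply(model$nodes, function(n) walk_params(n$module)),
                    recursive = FALSE)
  list(handles = handles, step = 0L,
       m = lapply(handles, function(h) h$env$params[[h$name]] * 0),
       v = lapply(handles, function(h) h$env$params[[h$name]] * 0))
}

# decay applies to 2-D weight matrices only (convolution kernels, MLPs)
wd_applies <- function(h) {
  is.matrix(h$env$params[[h$name]]) && !startsWith(h$name, "bn_")
}

adamw_step <- function(opt, lr, cfg) {
  opt$step <- opt$step + 1L
  b1 <- cfg$momentum; b2 <- cfg$beta2
  bc1 <- 1 - b1^opt$step
  bc2 <- 1 - b2^opt$step
  for (i in seq_along(opt$handles)) {
    h <- opt$handles[[i]]
    g <- h$env$grads[[h$name]]
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
    upd <- (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + 1e-8)
    p <- h$env$params[[h$name]]
    if (wd_applies(h)) p <- p - lr * cfg$weight_decay * p
    h$env$params[[h$name]] <- p - lr * upd
  }
  opt
}

# letterbox one sample (image + normalised boxes) onto the training canvas
prepare_sample <- function(img, boxes, size) {
  lb <- letterbox_image(img, size)
  d <- dim(img)
  px <- yolo_to_pixels(boxes, d[2L], d[1L])
  px$x1 <- px$x1 * lb$scale + lb$pad[["x"]]
  px$x2 <- px$x2 * lb$scale + lb$pad[["x"]]
  px$y1 <- px$y1 * lb$scale + lb$pad[["y"]]
  px$y2 <- px$y2 * lb$scale + lb$pad[["y"]]
  list(image = lb$image, boxes = pixels_to_yolo(px, size, size))
}

hflip_sample <- function(s) {
  s$image <- s$image[, rev(seq_len(dim(s$image)[2L])), , drop = FALSE]
  s$boxes$cx <- 1 - s$boxes$cx
  s
}

#' Train a detector
#'
#' Minimal seeded loop: letterboxes the dataset once, then runs AdamW steps
#' over shuffled mini-batches with a linear learning-rate decay.  Training
#' aborts with the accumulated history if the loss diverges (> 1e4) or a
#' component becomes non-finite.
#'
#' @param model an `lsd_model` (modified in place and returned).
#' @param dataset list of samples `list(image = (H, W, 3) array or PNG path,
#'   boxes = normalised box data.frame)`.
#' @param config a [train_config()].
#' @param iterations total optimizer-step horizon of the run (also the
#'   learning-rate decay horizon); overrides `config$epochs`.
#' @param stop_after optionally stop this call after that many steps while
#'   keeping the full-horizon schedule, so training can be checkpointed and
#'   resumed to replay an uninterrupted run exactly.
#' @param eval_data optional dataset evaluated (mAP) at the end of training.
#' @param verbose print a progress line every 20 steps.
#' @return list: `model`, `history` (per-step loss components), `opt`
#'   (optimizer state for resuming), `eval` (optional final report).
#' @export
fit <- function(model, dataset, config = train_config(), iterations = NULL,
                stop_after = NULL, eval_data = NULL, verbose = FALSE,
                opt = NULL) {
  stopifnot(inherits(model, "lsd_model"), length(dataset) >= 1)
  size <- config$input_size
  if (size %% max(model$strides) != 0)
    stop("input_size must be divisible by the maximum stride")
  prepped <- lapply(dataset, function(s) {
    img <- if (is.character(s$image)) png::readPNG(s$image)[, , 1:3, drop = FALSE]
           else s$image
    prepare_sample(img, s$boxes, size)
  })
  n <- length(prepped)
  steps_per_epoch <- ceiling(n / config$batch_size)
  total_steps <- if (is.null(iterations)) config$epochs * steps_per_epoch
                 else as.integer(iterations)
  if (is.null(opt)) opt <- adamw_init(model)
  history <- data.frame(step = integer(0), lr = numeric(0), total = numeric(0),
                        box = numeric(0), cls = numeric(0), dfl = numeric(0))
  nc <- model$variant$num_classes
  # epoch shuffles and per-step flips are seeded independently of the step
  # at which training (re)starts, so a resumed run replays an uninterrupted
  # one exactly
  cur_epoch <- -1L; ord <- NULL
  if (opt$step >= total_steps && total_steps > 0)
    warning("checkpoint already at ", opt$step, " steps; nothing to do")
  last_step <- if (is.null(stop_after)) total_steps
               else min(total_steps, opt$step + as.integer(stop_after))
  for (step0 in seq_len(max(last_step - opt$step, 0L)) - 1L + opt$step) {
    epoch <- step0 %/% steps_per_epoch
    bi <- step0 %% steps_per_epoch
    if (epoch != cur_epoch) {
      ord <- with_local_seed(config$seed + epoch, sample.int(n))
      cur_epoch <- epoch
    }
    idx <- ord[(bi * config$batch_size + 1L):min((bi + 1L) * config$batch_size, n)]
    batch <- prepped[idx]
    if (config$flip_augment) {
      flips <- with_local_seed(config$seed + 100003L + step0,
                               runif(length(batch)) < 0.5)
      batch <- lapply(seq_along(batch), function(j)
        if (flips[j]) hflip_sample(batch[[j]]) else batch[[j]])
    }
    x <- array(0, c(size, size, 3L, length(batch)))
    tlist <- list()
    for (j in seq_along(batch)) {
      x[, , , j] <- batch[[j]]$image
      bx <- batch[[j]]$boxes
      if (nrow(bx)) tlist[[length(tlist) + 1L]] <- cbind(image = j, bx)
    }
    targets <- if (length(tlist)) do.call(rbind, tlist)
               else cbind(image = integer(0), empty_boxes())
    fh <- forward_heads(model, x, train = TRUE)
    ls <- compute_loss(fh$head, targets, model$strides, size,
                       model$reg_max, nc)
    for (node in model$nodes) zero_grads(node$module)
    backward_graph(model, fh$outs, ls$dhead)
    lr <- config$lr0 * (1 - (step0 / total_steps) * (1 - config$lrf))
    opt <- adamw_step(opt, lr, config)
    history[nrow(history) + 1L, ] <- c(step0 + 1L, lr, ls$total, ls$box,
                                       ls$cls, ls$dfl)
    if (verbose && (step0 + 1L) %% 20L == 0L)
      message(sprintf("step %4d  lr %.5f  loss %.4f (box %.3f cls %.3f dfl %.3f)",
                      step0 + 1L, lr, ls$total, ls$box, ls$cls, ls$dfl))
    if (!is.finite(ls$total) || ls$total > 1e4) {
      warning("training diverged at step ", step0 + 1L, "; aborting")
      return(list(model = model, history = history, opt = opt,
                  diverged = TRUE))
    }
  }
  out <- list(model = model, history = history, opt = opt, config = config)
  if (!is.null(eval_data))
    out$eval <- evaluate_model(model, eval_data, input_size = size)
  out
}

#' Evaluate a model on a labelled dataset
#'
#' Letterboxes each image, decodes predictions at the evaluation operating
#' point (confidence floor 0.001, NMS IoU 0.7 by default) and scores them
#' against the ground truth with [evaluate_detections()].
#'
#' @param model an `lsd_model`.
#' @param dataset list of samples as in [fit()].
#' @param conf,iou decode thresholds.
#' @param input_size evaluation canvas (defaults to the variant's).
#' @return an `lsd_eval_report`.
#' @export
evaluate_model <- function(model, dataset, conf = 0.001, iou = 0.7,
                           input_size = NULL) {
  size <- if (is.null(input_size)) model$variant$input_size else input_size
  dets <- list(); gts <- list()
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    img <- if (is.character(s$image)) png::readPNG(s$image)[, , 1:3, drop = FALSE]
           else s$image
    ps <- prepare_sample(img, s$boxes, size)
    x <- array(ps$image, c(size, size, 3L, 1L))
    fh <- forward_heads(model, x, train = FALSE)
    dets[[i]] <- decode_predictions(fh$head, conf, iou,
                                    strides = model$strides,
                                    reg_max = model$reg_max)[[1L]]
    gts[[i]] <- yolo_to_pixels(ps$boxes, size, size)
  }
  evaluate_detections(dets, gts)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a self-describing RDS container holding the variant
#' config, all parameter and buffer arrays (in graph order), and optionally
#' the optimizer state, so training can resume deterministically.
#'
#' @param model an `lsd_model`.
#' @param path file path.
#' @param opt optional optimizer state from [fit()].
#' @return `load_checkpoint` returns `list(model, opt)`.
#' @export
save_checkpoint <- function(model, path, opt = NULL) {
  grab <- function(mod) list(params = mod$params, buffers = mod$buffers,
                             children = lapply(mod$children, grab))
  state <- lapply(model$nodes, function(n) grab(n$module))
  opt_state <- NULL
  if (!is.null(opt))
    opt_state <- list(step = opt$step, m = opt$m, v = opt$v)
  saveRDS(list(variant = model$variant, seed = model$seed, state = state,
               opt = opt_state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$variant, seed = ck$seed)
  put <- function(mod, st) {
    mod$params <- st$params
    mod$buffers <- st$buffers
    for (nm in names(st$children)) put(mod$children[[nm]], st$children[[nm]])
  }
  for (nm in names(ck$state)) put(model$nodes[[nm]]$module, ck$state[[nm]])
  opt <- NULL
  if (!is.null(ck$opt)) {
    opt <- adamw_init(model)
    opt$step <- ck$opt$step
    opt$m <- ck$opt$m
    opt$v <- ck$opt$v
  }
  list(model = model, opt = opt)
}
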