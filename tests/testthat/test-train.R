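# Loss behaviour and the training loop (kept small: tiny inputs, few steps).

make_tiny_model <- function(input = 64, seed = 0) {
  build_model(model_variant(use_sac = TRUE, use_sod = TRUE, use_cbam = TRUE,
                            input_size = input), seed = seed)
}

test_that("loss components are finite, non-negative and well-behaved", {
  m <- make_tiny_model()
  set.seed(50)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  fh <- forward_heads(m, x, train = TRUE)
  # image 1 has a target, image 2 none
  tg <- data.frame(image = 1, class_id = 0L, cx = 0.5, cy = 0.5, w = 0.5, h = 0.5)
  ls <- compute_loss(fh$head, tg, m$strides, 64, m$reg_max, 2L)
  expect_true(all(is.finite(c(ls$total, ls$box, ls$cls, ls$dfl))))
  expect_gte(ls$box, 0); expect_gte(ls$cls, 0); expect_gte(ls$dfl, 0)
  expect_gt(ls$fg, 0)
  # no targets anywhere: zero box/dfl loss, classification from background
  ls0 <- compute_loss(fh$head, tg[0, ], m$strides, 64, m$reg_max, 2L)
  expect_equal(ls0$box, 0)
  expect_equal(ls0$dfl, 0)
  expect_gt(ls0$cls, 0)
  expect_equal(ls0$fg, 0L)
  # duplicate identical targets assign without error (degenerate input)
  tg2 <- rbind(tg, tg)
  expect_no_error(compute_loss(fh$head, tg2, m$strides, 64, m$reg_max, 2L))
})

test_that("zero learning rate leaves every parameter unchanged", {
  m <- make_tiny_model(seed = 1)
  ds <- tiny_dataset(2, canvas = 64, seed = 600)
  before <- lapply(m$nodes, function(n)
    lapply(walk_params(n$module), function(h) h$env$params[[h$name]]))
  cfg <- train_config(lr0 = 1e-12, weight_decay = 0, input_size = 64,
                      batch_size = 2, seed = 0)
  fit(m, ds, cfg, iterations = 2)
  after <- lapply(m$nodes, function(n)
    lapply(walk_params(n$module), function(h) h$env$params[[h$name]]))
  expect_equal(before, after, tolerance = 1e-9)
})

test_that("one optimizer step changes every tensor that received gradient", {
  m <- make_tiny_model(seed = 2)
  ds <- tiny_dataset(2, canvas = 64, seed = 610)
  handles <- unlist(lapply(m$nodes, function(n) walk_params(n$module)),
                    recursive = FALSE)
  before <- lapply(handles, function(h) h$env$params[[h$name]])
  cfg <- train_config(input_size = 64, batch_size = 2, seed = 0)
  fit(m, ds, cfg, iterations = 1)
  changed <- vapply(seq_along(handles), function(i) {
    h <- handles[[i]]
    g <- h$env$grads[[h$name]]
    p <- h$env$params[[h$name]]
    !any(g != 0) || any(p != before[[i]])
  }, logical(1))
  expect_true(all(changed))
  # and most tensors do receive gradient
  got_grad <- vapply(handles, function(h) any(h$env$grads[[h$name]] != 0),
                     logical(1))
  expect_gt(mean(got_grad), 0.95)
})

test_that("short training reduces the loss in trend", {
  m <- make_tiny_model(seed = 3)
  ds <- tiny_dataset(2, canvas = 64, seed = 620, n_targets = 2,
                     occlusion_prob = 0)
  cfg <- train_config(input_size = 64, batch_size = 2, seed = 0)
  res <- fit(m, ds, cfg, iterations = 30)
  expect_false(isTRUE(res$diverged))
  expect_lt(mean(tail(res$history$total, 10)), mean(head(res$history$total, 10)))
})

test_that("checkpoint resume replays an uninterrupted run exactly", {
  ds <- tiny_dataset(2, canvas = 64, seed = 630)
  cfg <- train_config(input_size = 64, batch_size = 2, seed = 9)
  # uninterrupted: 6 steps
  m1 <- make_tiny_model(seed = 4)
  r1 <- fit(m1, ds, cfg, iterations = 6)
  # interrupted: 3 of 6 steps under the same schedule horizon, checkpoint to
  # disk, reload, finish
  m2 <- make_tiny_model(seed = 4)
  r2a <- fit(m2, ds, cfg, iterations = 6, stop_after = 3)
  ck <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(r2a$model, ck, r2a$opt)
  loaded <- load_checkpoint(ck)
  r2b <- fit(loaded$model, ds, cfg, iterations = 6, opt = loaded$opt)
  expect_equal(r2b$history$total, r1$history$total[4:6], tolerance = 1e-10)
  p1 <- count_parameters(r1$model)
  expect_equal(p1, count_parameters(r2b$model))
  h1 <- unlist(lapply(r1$model$nodes, function(n)
    lapply(walk_params(n$module), function(h) h$env$params[[h$name]])))
  h2 <- unlist(lapply(r2b$model$nodes, function(n)
    lapply(walk_params(n$module), function(h) h$env$params[[h$name]])))
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("training is reproducible across runs with the same seed", {
  ds <- tiny_dataset(2, canvas = 64, seed = 640)
  cfg <- train_config(input_size = 64, batch_size = 2, seed = 13)
  r1 <- fit(make_tiny_model(seed = 5), ds, cfg, iterations = 3)
  r2 <- fit(make_tiny_model(seed = 5), ds, cfg, iterations = 3)
  expect_identical(r1$history$total, r2$history$total)
})
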