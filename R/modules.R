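# Network modules.  Each module is an environment holding `params` (trainable
# arrays), `grads` (accumulated, same shapes), optional `buffers` (batch-norm
# running statistics) and a forward cache.  Composite modules hold `children`.
# Dispatch is S3 on the module class: m_fwd() / m_bwd().

new_module <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  e$buffers <- list()
  e$children <- list()
  e$cache <- NULL
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("mod_", type), "lsd_module")
  e
}

# Kaiming-uniform conv weight, stored (Cin*k*k) x Cout
init_conv_w <- function(c1, c2, k) {
  fan_in <- c1 * k * k
  bound <- sqrt(6 / fan_in)
  matrix(runif(fan_in * c2, -bound, bound), fan_in, c2)
}

zero_like_params <- function(params) lapply(params, function(p) p * 0)

m_fwd <- function(mod, x, train = FALSE) UseMethod("m_fwd")
m_bwd <- function(mod, dout) UseMethod("m_bwd")

## ---- plain conv2d (+ optional bias), no norm / activation -----------------

mk_conv2d <- function(c1, c2, k = 1, stride = 1, pad = NULL, dil = 1, bias = TRUE) {
  if (is.null(pad)) pad <- dil * (k - 1) %/% 2
  m <- new_module("conv2d", c1 = c1, c2 = c2, k = k, stride = stride,
                  pad = pad, dil = dil, has_bias = bias)
  m$params$w <- init_conv_w(c1, c2, k)
  if (bias) m$params$b <- numeric(c2)
  m$grads <- zero_like_params(m$params)
  m
}

m_fwd.mod_conv2d <- function(mod, x, train = FALSE) {
  mod$cache <- list(x = x)
  cpp_conv2d_fw(x, mod$params$w,
                if (mod$has_bias) mod$params$b else numeric(0),
                mod$k, mod$stride, mod$pad, mod$dil)
}

m_bwd.mod_conv2d <- function(mod, dout) {
  g <- cpp_conv2d_bw(mod$cache$x, mod$params$w, dout,
                     mod$k, mod$stride, mod$pad, mod$dil, TRUE, mod$has_bias)
  mod$grads$w <- mod$grads$w + g$dw
  if (mod$has_bias) mod$grads$b <- mod$grads$b + g$db
  g$dx
}

## ---- Conv block: conv (no bias) + BN + SiLU -------------------------------

mk_convblock <- function(c1, c2, k = 1, stride = 1, dil = 1) {
  m <- new_module("convblock", c1 = c1, c2 = c2, k = k, stride = stride,
                  dil = dil, pad = dil * (k - 1) %/% 2)
  m$params$w <- init_conv_w(c1, c2, k)
  m$params$bn_g <- rep(1, c2)
  m$params$bn_b <- numeric(c2)
  m$buffers$rm <- numeric(c2)
  m$buffers$rv <- rep(1, c2)
  m$grads <- zero_like_params(m$params)
  m
}

# fused BN + SiLU on top of a conv output; updates running stats in training
bn_silu_head <- function(mod, z, train) {
  if (train) {
    st <- cpp_bn_stats(z)
    mu <- st$mean
    va <- st$var
    d <- dim(z)
    n_el <- d[1L] * d[2L] * d[4L]
    mod$buffers$rm <- (1 - bn_momentum) * mod$buffers$rm + bn_momentum * mu
    mod$buffers$rv <- (1 - bn_momentum) * mod$buffers$rv +
      bn_momentum * va * n_el / max(n_el - 1, 1)
  } else {
    mu <- mod$buffers$rm
    va <- mod$buffers$rv
  }
  istd <- 1 / sqrt(va + bn_eps)
  list(y = cpp_bn_silu_fw(z, mod$params$bn_g, mod$params$bn_b, mu, istd),
       mu = mu, istd = istd)
}

m_fwd.mod_convblock <- function(mod, x, train = FALSE) {
  r <- cpp_convblock_fw(x, mod$params$w, mod$params$bn_g, mod$params$bn_b,
                        mod$buffers$rm, mod$buffers$rv,
                        mod$k, mod$stride, mod$pad, mod$dil,
                        train, bn_momentum, bn_eps,
                        if (is.null(mod$cc)) NULL else mod$cc)
  mod$cc <- r$cache
  if (train) { mod$buffers$rm <- r$rm; mod$buffers$rv <- r$rv }
  mod$cache <- list(cc = r$cache, mu = r$mu, istd = r$istd, train = train)
  r$y
}

m_bwd.mod_convblock <- function(mod, dout) {
  cc <- mod$cache
  g <- cpp_convblock_bw(dout, cc$cc, mod$params$w,
                        mod$params$bn_g, mod$params$bn_b, cc$mu, cc$istd,
                        mod$k, mod$stride, mod$pad, mod$dil,
                        cc$train, !isTRUE(mod$is_input_layer))
  mod$grads$bn_g <- mod$grads$bn_g + g$dg
  mod$grads$bn_b <- mod$grads$bn_b + g$db
  mod$grads$w <- mod$grads$w + g$dw
  g$dx
}

## ---- Bottleneck (two 3x3 conv blocks, optional residual) ------------------

mk_bottleneck <- function(c, shortcut = TRUE) {
  m <- new_module("bottleneck", add = shortcut)
  m$children$cv1 <- mk_convblock(c, c, 3, 1)
  m$children$cv2 <- mk_convblock(c, c, 3, 1)
  m
}

m_fwd.mod_bottleneck <- function(mod, x, train = FALSE) {
  y <- m_fwd(mod$children$cv2, m_fwd(mod$children$cv1, x, train), train)
  if (mod$add) y + x else y
}

m_bwd.mod_bottleneck <- function(mod, dout) {
  dx <- m_bwd(mod$children$cv1, m_bwd(mod$children$cv2, dout))
  if (mod$add) dx + dout else dx
}

## ---- C2f: split-transform-concat block ------------------------------------

mk_c2f <- function(c1, c2, n = 1, shortcut = FALSE) {
  c <- c2 %/% 2
  m <- new_module("c2f", c_hidden = c, n = n)
  m$children$cv1 <- mk_convblock(c1, 2 * c, 1, 1)
  m$children$cv2 <- mk_convblock((2 + n) * c, c2, 1, 1)
  for (i in seq_len(n)) m$children[[paste0("m", i)]] <- mk_bottleneck(c, shortcut)
  m
}

c2f_body <- function(mod, y0, train) {
  c <- mod$c_hidden
  ys <- split_c(y0, c(c, c))
  for (i in seq_len(mod$n))
    ys[[length(ys) + 1L]] <- m_fwd(mod$children[[paste0("m", i)]], ys[[length(ys)]], train)
  m_fwd(mod$children$cv2, concat_c(ys), train)
}

c2f_body_bw <- function(mod, dout) {
  c <- mod$c_hidden
  dcat <- m_bwd(mod$children$cv2, dout)
  parts <- split_c(dcat, rep(c, 2 + mod$n))
  dlast <- parts[[2 + mod$n]]
  for (i in rev(seq_len(mod$n))) {
    dprev <- m_bwd(mod$children[[paste0("m", i)]], dlast)
    dlast <- parts[[1 + i]] + dprev
  }
  concat_c(list(parts[[1L]], dlast))
}

m_fwd.mod_c2f <- function(mod, x, train = FALSE) {
  y0 <- m_fwd(mod$children$cv1, x, train)
  c2f_body(mod, y0, train)
}

m_bwd.mod_c2f <- function(mod, dout) {
  m_bwd(mod$children$cv1, c2f_body_bw(mod, dout))
}

## ---- SPPF -----------------------------------------------------------------

mk_sppf <- function(c1, c2, k = 5) {
  ch <- c1 %/% 2
  m <- new_module("sppf", k = k)
  m$children$cv1 <- mk_convblock(c1, ch, 1, 1)
  m$children$cv2 <- mk_convblock(4 * ch, c2, 1, 1)
  m
}

m_fwd.mod_sppf <- function(mod, x, train = FALSE) {
  y <- m_fwd(mod$children$cv1, x, train)
  p <- (mod$k - 1) %/% 2
  m1 <- cpp_maxpool_fw(y, mod$k, 1, p)
  m2 <- cpp_maxpool_fw(m1$out, mod$k, 1, p)
  m3 <- cpp_maxpool_fw(m2$out, mod$k, 1, p)
  mod$cache <- list(ydim = dim(y), i1 = m1$idx, i2 = m2$idx, i3 = m3$idx)
  m_fwd(mod$children$cv2, concat_c(list(y, m1$out, m2$out, m3$out)), train)
}

m_bwd.mod_sppf <- function(mod, dout) {
  cc <- mod$cache
  ch <- cc$ydim[3L]
  dcat <- m_bwd(mod$children$cv2, dout)
  parts <- split_c(dcat, rep(ch, 4))
  d3 <- cpp_maxpool_bw(parts[[4L]], cc$i3, cc$ydim)
  d2 <- cpp_maxpool_bw(parts[[3L]] + d3, cc$i2, cc$ydim)
  d1 <- cpp_maxpool_bw(parts[[2L]] + d2, cc$i1, cc$ydim)
  m_bwd(mod$children$cv1, parts[[1L]] + d1)
}

## ---- nearest upsample x2 --------------------------------------------------

mk_upsample2 <- function() new_module("upsample2")
m_fwd.mod_upsample2 <- function(mod, x, train = FALSE) cpp_upsample2_fw(x)
m_bwd.mod_upsample2 <- function(mod, dout) cpp_upsample2_bw(dout)

## ---- concat over channels (multi-input node) ------------------------------

mk_concat <- function() new_module("concat")
m_fwd.mod_concat <- function(mod, x, train = FALSE) {
  mod$cache <- list(sizes = vapply(x, function(z) dim(z)[3L], integer(1)))
  concat_c(x)
}
m_bwd.mod_concat <- function(mod, dout) split_c(dout, mod$cache$sizes)

## ---- decoupled anchor-free detection head ---------------------------------

mk_detect <- function(nc, ch, reg_max = 16) {
  c2 <- max(16, ch[1L] %/% 4, reg_max * 4)
  c3 <- max(ch[1L], min(nc, 100))
  m <- new_module("detect", nc = nc, reg_max = reg_max, nl = length(ch),
                  c2 = c2, c3 = c3)
  for (l in seq_along(ch)) {
    m$children[[paste0("box", l, "a")]] <- mk_convblock(ch[l], c2, 3, 1)
    m$children[[paste0("box", l, "b")]] <- mk_convblock(c2, c2, 3, 1)
    m$children[[paste0("box", l, "c")]] <- mk_conv2d(c2, 4 * reg_max, 1, bias = TRUE)
    m$children[[paste0("cls", l, "a")]] <- mk_convblock(ch[l], c3, 3, 1)
    m$children[[paste0("cls", l, "b")]] <- mk_convblock(c3, c3, 3, 1)
    m$children[[paste0("cls", l, "c")]] <- mk_conv2d(c3, nc, 1, bias = TRUE)
  }
  m
}

m_fwd.mod_detect <- function(mod, x, train = FALSE) {
  lapply(seq_len(mod$nl), function(l) {
    xi <- x[[l]]
    list(
      box = m_fwd(mod$children[[paste0("box", l, "c")]],
              m_fwd(mod$children[[paste0("box", l, "b")]],
                m_fwd(mod$children[[paste0("box", l, "a")]], xi, train), train), train),
      cls = m_fwd(mod$children[[paste0("cls", l, "c")]],
              m_fwd(mod$children[[paste0("cls", l, "b")]],
                m_fwd(mod$children[[paste0("cls", l, "a")]], xi, train), train), train))
  })
}

m_bwd.mod_detect <- function(mod, dout) {
  lapply(seq_len(mod$nl), function(l) {
    dbox <- m_bwd(mod$children[[paste0("box", l, "a")]],
              m_bwd(mod$children[[paste0("box", l, "b")]],
                m_bwd(mod$children[[paste0("box", l, "c")]], dout[[l]]$box)))
    dcls <- m_bwd(mod$children[[paste0("cls", l, "a")]],
              m_bwd(mod$children[[paste0("cls", l, "b")]],
                m_bwd(mod$children[[paste0("cls", l, "c")]], dout[[l]]$cls)))
    dbox + dcls
  })
}

## ---- parameter bookkeeping ------------------------------------------------

# Flat list of parameter handles: list(env, name, path)
walk_params <- function(mod, path = "") {
  out <- list()
  for (nm in names(mod$params)) {
    out[[length(out) + 1L]] <- list(env = mod, name = nm,
                                    path = paste0(path, "/", nm))
  }
  for (cn in names(mod$children)) {
    out <- c(out, walk_params(mod$children[[cn]], paste0(path, "/", cn)))
  }
  out
}

module_n_params <- function(mod) {
  sum(vapply(walk_params(mod), function(h) length(h$env$params[[h$name]]), numeric(1)))
}

zero_grads <- function(mod) {
  for (h in walk_params(mod)) h$env$grads[[h$name]] <- h$env$grads[[h$name]] * 0
  invisible(NULL)
}
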