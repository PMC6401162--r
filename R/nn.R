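# Layer-level plumbing for the generator/discriminator. Parameters live in a
# flat named list of arrays; forward passes cache pre-activations for the
# hand-written backward passes. Single-sample passes; batching is an outer
# loop with gradient accumulation.

# leaky ReLU, slope 0.1: 0.55 x + 0.45 |x| avoids branching
lrelu <- function(x) 0.55 * x + 0.45 * abs(x)
lrelu_grad <- function(x) 0.55 + 0.45 * sign(x)

.he_conv <- function(k, ci, co, gain = sqrt(2)) {
  array(rnorm(k * k * ci * co, 0, gain / sqrt(k * k * ci)), c(k, k, ci, co))
}

#' Generator (U-Net) configuration
#'
#' A U-Net variant with additional residual connections: a conv stem, `depth`
#' encoder levels (residual blocks, 2x average pool, channel doubling), a
#' residual bottleneck, and a mirrored decoder using 2x2 stride-2 transposed
#' convolutions with skip concatenation, ending in a linear RGB head (the
#' regression target lives in [0, 1]; outputs are clipped there only at
#' inference, keeping the L1 gradient alive on near-saturated backgrounds).
#' Input is the backpropagated complex field as 2 channels (Re, Im);
#' output is a 3-channel bright-field-like image in [0, 1].
#'
#' @param depth number of down/up levels (default 4).
#' @param base_channels channels at the first level (default 32).
#' @param residual_blocks residual blocks per level (default 2).
#' @return a `generator_config` list.
#' @export
generator_config <- function(depth = 4, base_channels = 32,
                             residual_blocks = 2) {
  stopifnot(depth >= 1, base_channels >= 1, residual_blocks >= 0)
  structure(list(depth = depth, base_channels = base_channels,
                 residual_blocks = residual_blocks,
                 in_channels = 2L, out_channels = 3L),
            class = "generator_config")
}

#' Discriminator configuration
#'
#' A convolutional classifier with six convolutional blocks (3x3 conv,
#' leaky ReLU, 2x average pool) and two fully connected layers after global
#' average pooling.
#'
#' @param base_channels channels of the first block (default 32).
#' @return a `discriminator_config` list.
#' @export
discriminator_config <- function(base_channels = 32) {
  structure(list(conv_blocks = 6L, fc_layers = 2L,
                 base_channels = base_channels),
            class = "discriminator_config")
}

# channel width at encoder level l (0-based)
.gchan <- function(cfg, l) cfg$base_channels * 2^l

generator_init <- function(cfg) {
  p <- list()
  add_conv <- function(name, ci, co, gain = sqrt(2)) {
    p[[paste0(name, ".W")]] <<- .he_conv(3, ci, co, gain)
    p[[paste0(name, ".b")]] <<- numeric(co)
  }
  add_conv("stem", cfg$in_channels, .gchan(cfg, 0))
  for (l in seq_len(cfg$depth) - 1) {
    for (r in seq_len(cfg$residual_blocks)) {
      add_conv(sprintf("enc%d_rb%d_c1", l, r), .gchan(cfg, l), .gchan(cfg, l))
      add_conv(sprintf("enc%d_rb%d_c2", l, r), .gchan(cfg, l), .gchan(cfg, l),
               gain = 0.5)
    }
    add_conv(sprintf("down%d", l), .gchan(cfg, l), .gchan(cfg, l + 1))
  }
  for (r in seq_len(cfg$residual_blocks)) {
    add_conv(sprintf("bott_rb%d_c1", r), .gchan(cfg, cfg$depth),
             .gchan(cfg, cfg$depth))
    add_conv(sprintf("bott_rb%d_c2", r), .gchan(cfg, cfg$depth),
             .gchan(cfg, cfg$depth), gain = 0.5)
  }
  for (l in rev(seq_len(cfg$depth) - 1)) {
    ci <- .gchan(cfg, l + 1); co <- .gchan(cfg, l)
    p[[sprintf("up%d.W", l)]] <- array(rnorm(4 * ci * co, 0,
                                             sqrt(2) / sqrt(4 * ci)),
                                       c(2, 2, ci, co))
    p[[sprintf("up%d.b", l)]] <- numeric(co)
    add_conv(sprintf("fuse%d", l), 2 * co, co)
    for (r in seq_len(cfg$residual_blocks)) {
      add_conv(sprintf("dec%d_rb%d_c1", l, r), co, co)
      add_conv(sprintf("dec%d_rb%d_c2", l, r), co, co, gain = 0.5)
    }
  }
  add_conv("head", .gchan(cfg, 0), cfg$out_channels, gain = 1)
  # start at the white background level: bright-field targets are mostly 1,
  # so the head bias opens at the target mean rather than at black
  p[["head.b"]] <- rep(1, cfg$out_channels)
  p
}

# residual block forward: x + c2(lrelu(c1(lrelu(x))))
.rb_fwd <- function(p, name, x, cache) {
  a1 <- lrelu(x)
  y1 <- cpp_conv2d_fwd(a1, p[[paste0(name, "_c1.W")]],
                       p[[paste0(name, "_c1.b")]])
  a2 <- lrelu(y1)
  y2 <- cpp_conv2d_fwd(a2, p[[paste0(name, "_c2.W")]],
                       p[[paste0(name, "_c2.b")]])
  cache[[name]] <- list(x = x, a1 = a1, y1 = y1, a2 = a2)
  list(y = x + y2, cache = cache)
}

.rb_bwd <- function(p, name, cache, gy, grads) {
  cc <- cache[[name]]
  b2 <- cpp_conv2d_bwd(cc$a2, p[[paste0(name, "_c2.W")]], gy)
  grads[[paste0(name, "_c2.W")]] <- grads[[paste0(name, "_c2.W")]] + b2$gw
  grads[[paste0(name, "_c2.b")]] <- grads[[paste0(name, "_c2.b")]] + b2$gb
  gy1 <- b2$gx * lrelu_grad(cc$y1)
  b1 <- cpp_conv2d_bwd(cc$a1, p[[paste0(name, "_c1.W")]], gy1)
  grads[[paste0(name, "_c1.W")]] <- grads[[paste0(name, "_c1.W")]] + b1$gw
  grads[[paste0(name, "_c1.b")]] <- grads[[paste0(name, "_c1.b")]] + b1$gb
  list(gx = gy + b1$gx * lrelu_grad(cc$x), grads = grads)
}

generator_forward <- function(p, cfg, x, keep_cache = FALSE) {
  cache <- list(x_in = x)
  y <- cpp_conv2d_fwd(x, p[["stem.W"]], p[["stem.b"]])
  cache$stem_y <- y
  h <- lrelu(y)
  skips <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth) - 1) {
    for (r in seq_len(cfg$residual_blocks)) {
      res <- .rb_fwd(p, sprintf("enc%d_rb%d", l, r), h, cache)
      h <- res$y; cache <- res$cache
    }
    skips[[l + 1]] <- h
    pooled <- cpp_avgpool_fwd(h)
    y <- cpp_conv2d_fwd(pooled, p[[sprintf("down%d.W", l)]],
                        p[[sprintf("down%d.b", l)]])
    cache[[sprintf("down%d", l)]] <- list(pooled = pooled, y = y)
    h <- lrelu(y)
  }
  for (r in seq_len(cfg$residual_blocks)) {
    res <- .rb_fwd(p, sprintf("bott_rb%d", r), h, cache)
    h <- res$y; cache <- res$cache
  }
  for (l in rev(seq_len(cfg$depth) - 1)) {
    yu <- cpp_upconv_fwd(h, p[[sprintf("up%d.W", l)]],
                         p[[sprintf("up%d.b", l)]])
    cache[[sprintf("up%d", l)]] <- list(x = h, y = yu)
    hu <- lrelu(yu)
    sk <- skips[[l + 1]]
    cat_in <- array(c(hu, sk), c(dim(hu)[1], dim(hu)[2],
                                 dim(hu)[3] + dim(sk)[3]))
    y <- cpp_conv2d_fwd(cat_in, p[[sprintf("fuse%d.W", l)]],
                        p[[sprintf("fuse%d.b", l)]])
    cache[[sprintf("fuse%d", l)]] <- list(cat_in = cat_in, y = y,
                                          n_up = dim(hu)[3])
    h <- lrelu(y)
    for (r in seq_len(cfg$residual_blocks)) {
      res <- .rb_fwd(p, sprintf("dec%d_rb%d", l, r), h, cache)
      h <- res$y; cache <- res$cache
    }
  }
  yh <- cpp_conv2d_fwd(h, p[["head.W"]], p[["head.b"]])
  cache$head <- list(x = h)
  if (keep_cache) list(y = yh, cache = cache) else list(y = yh)
}

generator_backward <- function(p, cfg, cache, g_out) {
  grads <- lapply(p, function(a) array(0, dim(a) %||% length(a)))
  bh <- cpp_conv2d_bwd(cache$head$x, p[["head.W"]], g_out)
  grads[["head.W"]] <- grads[["head.W"]] + bh$gw
  grads[["head.b"]] <- grads[["head.b"]] + bh$gb
  g <- bh$gx
  for (l in seq_len(cfg$depth) - 1) {             # decoder, shallow -> deep
    for (r in rev(seq_len(cfg$residual_blocks))) {
      res <- .rb_bwd(p, sprintf("dec%d_rb%d", l, r), cache, g, grads)
      g <- res$gx; grads <- res$grads
    }
    fz <- cache[[sprintf("fuse%d", l)]]
    gf <- g * lrelu_grad(fz$y)
    bf <- cpp_conv2d_bwd(fz$cat_in, p[[sprintf("fuse%d.W", l)]], gf)
    grads[[sprintf("fuse%d.W", l)]] <- grads[[sprintf("fuse%d.W", l)]] + bf$gw
    grads[[sprintf("fuse%d.b", l)]] <- grads[[sprintf("fuse%d.b", l)]] + bf$gb
    n_up <- fz$n_up
    g_hu <- bf$gx[, , seq_len(n_up), drop = FALSE]
    g_skip <- bf$gx[, , n_up + seq_len(dim(bf$gx)[3] - n_up), drop = FALSE]
    uz <- cache[[sprintf("up%d", l)]]
    gu <- g_hu * lrelu_grad(uz$y)
    bu <- cpp_upconv_bwd(uz$x, p[[sprintf("up%d.W", l)]], gu)
    grads[[sprintf("up%d.W", l)]] <- grads[[sprintf("up%d.W", l)]] + bu$gw
    grads[[sprintf("up%d.b", l)]] <- grads[[sprintf("up%d.b", l)]] + bu$gb
    g <- bu$gx
    if (l == cfg$depth - 1) {
      for (r in rev(seq_len(cfg$residual_blocks))) {
        res <- .rb_bwd(p, sprintf("bott_rb%d", r), cache, g, grads)
        g <- res$gx; grads <- res$grads
      }
    }
    # stash the skip gradient for the encoder pass
    cache[[sprintf("gskip%d", l)]] <- g_skip
  }
  for (l in rev(seq_len(cfg$depth) - 1)) {        # encoder, deep -> shallow
    dz <- cache[[sprintf("down%d", l)]]
    gd <- g * lrelu_grad(dz$y)
    bd <- cpp_conv2d_bwd(dz$pooled, p[[sprintf("down%d.W", l)]], gd)
    grads[[sprintf("down%d.W", l)]] <- grads[[sprintf("down%d.W", l)]] + bd$gw
    grads[[sprintf("down%d.b", l)]] <- grads[[sprintf("down%d.b", l)]] + bd$gb
    g <- cpp_avgpool_bwd(bd$gx) + cache[[sprintf("gskip%d", l)]]
    for (r in rev(seq_len(cfg$residual_blocks))) {
      res <- .rb_bwd(p, sprintf("enc%d_rb%d", l, r), cache, g, grads)
      g <- res$gx; grads <- res$grads
    }
  }
  gs <- g * lrelu_grad(cache$stem_y)
  bs <- cpp_conv2d_bwd(cache$x_in, p[["stem.W"]], gs)
  grads[["stem.W"]] <- grads[["stem.W"]] + bs$gw
  grads[["stem.b"]] <- grads[["stem.b"]] + bs$gb
  list(grads = grads, gx = bs$gx)
}

.dchan <- function(cfg, b) cfg$base_channels * 2^min((b - 1) %/% 2, 2)

discriminator_init <- function(cfg, in_channels = 3) {
  p <- list()
  ci <- in_channels
  for (b in seq_len(cfg$conv_blocks)) {
    co <- .dchan(cfg, b)
    p[[sprintf("d%d.W", b)]] <- .he_conv(3, ci, co)
    p[[sprintf("d%d.b", b)]] <- numeric(co)
    ci <- co
  }
  p[["fc1.W"]] <- matrix(rnorm(ci * ci, 0, sqrt(2 / ci)), ci, ci)
  p[["fc1.b"]] <- numeric(ci)
  p[["fc2.W"]] <- matrix(rnorm(ci, 0, 1 / sqrt(ci)), 1, ci)
  p[["fc2.b"]] <- 0
  p
}

discriminator_forward <- function(p, cfg, x, keep_cache = FALSE) {
  cache <- list()
  h <- x
  for (b in seq_len(cfg$conv_blocks)) {
    y <- cpp_conv2d_fwd(h, p[[sprintf("d%d.W", b)]], p[[sprintf("d%d.b", b)]])
    a <- lrelu(y)
    pooled <- if (dim(a)[1] >= 2 && dim(a)[2] >= 2) cpp_avgpool_fwd(a) else a
    cache[[sprintf("d%d", b)]] <- list(x = h, y = y, a_dim = dim(a),
                                       pooled_dim = dim(pooled))
    h <- pooled
  }
  v <- apply(h, 3, mean)                    # global average pool
  cache$gap <- list(h_dim = dim(h), v = v)
  z1 <- drop(p[["fc1.W"]] %*% v) + p[["fc1.b"]]
  a1 <- lrelu(z1)
  out <- as.numeric(p[["fc2.W"]] %*% a1) + as.numeric(p[["fc2.b"]])
  cache$fc <- list(v = v, z1 = z1, a1 = a1)
  if (keep_cache) list(y = out, cache = cache) else list(y = out)
}

discriminator_backward <- function(p, cfg, cache, g_out) {
  grads <- lapply(p, function(a) array(0, dim(a) %||% length(a)))
  fc <- cache$fc
  grads[["fc2.W"]] <- grads[["fc2.W"]] + g_out * matrix(fc$a1, 1)
  grads[["fc2.b"]] <- grads[["fc2.b"]] + g_out
  ga1 <- drop(t(p[["fc2.W"]])) * g_out
  gz1 <- ga1 * lrelu_grad(fc$z1)
  grads[["fc1.W"]] <- grads[["fc1.W"]] + outer(gz1, fc$v)
  grads[["fc1.b"]] <- grads[["fc1.b"]] + gz1
  gv <- drop(t(p[["fc1.W"]]) %*% gz1)
  hd <- cache$gap$h_dim
  g <- array(rep(gv / (hd[1] * hd[2]), each = hd[1] * hd[2]), hd)
  for (b in rev(seq_len(cfg$conv_blocks))) {
    cc <- cache[[sprintf("d%d", b)]]
    if (!identical(cc$a_dim, cc$pooled_dim)) g <- cpp_avgpool_bwd(g)
    gy <- g * lrelu_grad(cc$y)
    bb <- cpp_conv2d_bwd(cc$x, p[[sprintf("d%d.W", b)]], gy)
    grads[[sprintf("d%d.W", b)]] <- grads[[sprintf("d%d.W", b)]] + bb$gw
    grads[[sprintf("d%d.b", b)]] <- grads[[sprintf("d%d.b", b)]] + bb$gb
    g <- bb$gx
  }
  list(grads = grads, gx = g)
}

# Adam with standard bias correction; state carried in an environment
adam_make <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$m <- lapply(params, function(a) array(0, dim(a) %||% length(a)))
  e$v <- e$m
  e$t <- 0L
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e
}

adam_step <- function(st, params, grads) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t; bc2 <- 1 - st$beta2^st$t
  for (k in names(params)) {
    g <- grads[[k]]
    st$m[[k]] <- st$beta1 * st$m[[k]] + (1 - st$beta1) * g
    st$v[[k]] <- st$beta2 * st$v[[k]] + (1 - st$beta2) * g^2
    params[[k]] <- params[[k]] -
      st$lr * (st$m[[k]] / bc1) / (sqrt(st$v[[k]] / bc2) + st$eps)
  }
  params
}
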