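#' Training schedule configuration
#'
#' Defaults follow the reference training recipe: per iteration the
#' generator takes six Adam updates at learning rate 1e-4 and the
#' discriminator three at 3e-5; the validation set is scored every 50
#' iterations and the selected model is the one with the lowest validation
#' mean absolute error. `adversarial_weight = 0` disables the adversarial
#' term (pure-MAE training).
#'
#' @param gen_updates,disc_updates updates per iteration (defaults 6, 3).
#' @param lr_gen,lr_disc Adam learning rates (defaults 1e-4, 3e-5).
#' @param val_every validation period in iterations (default 50).
#' @param adversarial_weight weight of the least-squares adversarial term in
#'   the generator loss (default 0.02).
#' @param max_iterations training iterations (default 500).
#' @param batch_size patches per update (default 1).
#' @param seed master seed for initialization and data order.
#' @return a `training_config` list.
#' @export
training_config <- function(gen_updates = 6, disc_updates = 3,
                            lr_gen = 1e-4, lr_disc = 3e-5, val_every = 50,
                            adversarial_weight = 0.02, max_iterations = 500,
                            batch_size = 1, seed = 1) {
  stopifnot(lr_gen > 0, lr_disc > 0, adversarial_weight >= 0,
            val_every >= 1, max_iterations >= 1)
  structure(list(gen_updates = gen_updates, disc_updates = disc_updates,
                 lr_gen = lr_gen, lr_disc = lr_disc, val_every = val_every,
                 adversarial_weight = adversarial_weight,
                 max_iterations = max_iterations, batch_size = batch_size,
                 seed = seed),
            class = "training_config")
}

# complex patch -> (H, W, 2) array. The backpropagated background carries an
# arbitrary global phasor exp(i 2 pi z / lambda); aligning it to the real
# axis (multiplying by the conjugate unit mean phasor) makes the encoding
# independent of absolute height. Channels are then mean-centered and scaled
# by the mean amplitude (~1 for unit-mean holograms), a contrast-stable
# normalization that transfers between scenes of different object density.
encode_input <- function(patch) {
  mu <- mean(patch)
  phasor <- if (Mod(mu) > 1e-9) mu / Mod(mu) else 1 + 0i
  u <- patch * Conj(phasor)
  s <- mean(Mod(u))
  if (s < 1e-12) s <- 1
  x <- array(c(Re(u) - mean(Re(u)), Im(u) - mean(Im(u))),
             c(nrow(patch), ncol(patch), 2)) / s
  list(x = x, phasor = phasor, scale = s)
}

# dihedral group: k in 0..7; k %% 4 quarter-turns, k >= 4 adds a flip
.dihedral <- function(m, k) {
  if (k >= 4) m <- m[nrow(m):1, , drop = FALSE]
  for (i in seq_len(k %% 4)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}
.dihedral_arr <- function(a, k) {
  slices <- lapply(seq_len(dim(a)[3]), function(c) .dihedral(a[, , c], k))
  d1 <- dim(slices[[1]])
  array(unlist(slices), c(d1[1], d1[2], dim(a)[3]))
}

#' Augment patch pairs by random rotation and flipping
#'
#' Each pair yields itself plus `factor - 1` distinct transforms drawn
#' without replacement from the eight axis-aligned rotations/flips, applied
#' identically to input and target (the reference recipe's 5x augmentation,
#' ~6000 to 30,000 pairs).
#'
#' @param pairs list of pairs (`input` complex matrix, `target` RGB array).
#' @param factor total copies per pair, between 1 and 8 (default 5).
#' @param seed integer seed.
#' @return the augmented pair list, length `factor * length(pairs)`.
#' @export
augment_pairs <- function(pairs, factor = 5, seed = 1) {
  if (factor < 1 || factor > 8)
    stop("factor must be between 1 and 8 (dihedral group size)",
         call. = FALSE)
  if (factor == 1) return(pairs)
  with_seed(seed, {
    out <- list()
    for (pr in pairs) {
      ks <- c(0, sample(1:7, factor - 1))
      for (k in ks) {
        q <- pr
        q$input <- .dihedral(pr$input, k)
        q$target <- .dihedral_arr(pr$target, k)
        q$transform <- k
        out[[length(out) + 1]] <- q
      }
    }
    out
  })
}

.val_mae <- function(params, gcfg, val_enc) {
  maes <- vapply(val_enc, function(v) {
    y <- generator_forward(params, gcfg, v$x)$y
    mean(abs(y - v$t))
  }, numeric(1))
  mean(maes)
}

#' Train the cross-modality bright-field generator (GAN)
#'
#' Fits the holographic-to-bright-field image transformation: a residual
#' U-Net generator mapping backpropagated complex fields (Re, Im channels)
#' to bright-field-equivalent RGB patches, optionally with a least-squares
#' adversarial term from a convolutional discriminator. Per iteration the
#' generator is updated `gen_updates` times (loss
#' `MAE + adversarial_weight * (D(G(x)) - 1)^2`) and the discriminator
#' `disc_updates` times (`(D(real) - 1)^2 + D(fake)^2`). Checkpoints are
#' scored on the validation set every `val_every` iterations and the model
#' with the lowest validation MAE is returned. Fully deterministic for a
#' given seed.
#'
#' @param train_pairs,val_pairs pair lists as produced by
#'   [build_paired_dataset()] / [augment_pairs()].
#' @param gen_cfg a [generator_config()].
#' @param disc_cfg a [discriminator_config()].
#' @param train_cfg a [training_config()].
#' @param verbose print progress every validation (default FALSE).
#' @return an object of class `brightfield_gan` with elements `params`
#'   (selected weights), `history` (iteration/loss records), `gen_cfg`,
#'   `disc_cfg`, `train_cfg`.
#' @export
train_brightfield_gan <- function(train_pairs, val_pairs,
                                  gen_cfg = generator_config(),
                                  disc_cfg = discriminator_config(),
                                  train_cfg = training_config(),
                                  verbose = FALSE) {
  if (length(train_pairs) == 0 || length(val_pairs) == 0)
    stop("train and validation splits must be nonempty", call. = FALSE)
  d0 <- dim(train_pairs[[1]]$input)
  if (any(d0 %% 2^gen_cfg$depth != 0))
    stop("patch dims must be divisible by 2^depth", call. = FALSE)
  alpha <- train_cfg$adversarial_weight
  tr_enc <- lapply(train_pairs, function(pr)
    list(x = encode_input(pr$input)$x, t = pr$target))
  val_enc <- lapply(val_pairs, function(pr)
    list(x = encode_input(pr$input)$x, t = pr$target))
  history <- list()
  with_seed(train_cfg$seed, {
    gp <- generator_init(gen_cfg)
    dp <- if (alpha > 0) discriminator_init(disc_cfg) else NULL
    g_opt <- adam_make(gp, train_cfg$lr_gen)
    d_opt <- if (alpha > 0) adam_make(dp, train_cfg$lr_disc) else NULL
    mae0 <- .val_mae(gp, gen_cfg, val_enc)
    val_iters <- 0; val_maes <- mae0
    best <- gp; best_mae <- mae0; best_iter <- 0
    n_tr <- length(tr_enc)
    for (it in seq_len(train_cfg$max_iterations)) {
      g_losses <- numeric(0)
      for (u in seq_len(train_cfg$gen_updates)) {
        idx <- sample.int(n_tr, train_cfg$batch_size, replace = TRUE)
        grads <- NULL; loss_acc <- 0
        for (i in idx) {
          fw <- generator_forward(gp, gen_cfg, tr_enc[[i]]$x,
                                  keep_cache = TRUE)
          diff <- fw$y - tr_enc[[i]]$t
          loss <- mean(abs(diff))
          g_out <- sign(diff) / length(diff)
          if (alpha > 0) {
            dfw <- discriminator_forward(dp, disc_cfg, fw$y,
                                         keep_cache = TRUE)
            loss <- loss + alpha * (dfw$y - 1)^2
            db <- discriminator_backward(dp, disc_cfg, dfw$cache,
                                         alpha * 2 * (dfw$y - 1))
            g_out <- g_out + db$gx
          }
          bw <- generator_backward(gp, gen_cfg, fw$cache, g_out)
          grads <- if (is.null(grads)) bw$grads
                   else Map(`+`, grads, bw$grads)
          loss_acc <- loss_acc + loss
        }
        if (!is.finite(loss_acc))
          stop("generator loss diverged (non-finite)", call. = FALSE)
        if (length(idx) > 1)
          grads <- lapply(grads, function(g) g / length(idx))
        gp <- adam_step(g_opt, gp, grads)
        g_losses <- c(g_losses, loss_acc / length(idx))
      }
      d_loss <- NA_real_
      if (alpha > 0) {
        for (u in seq_len(train_cfg$disc_updates)) {
          i <- sample.int(n_tr, 1)
          fake <- generator_forward(gp, gen_cfg, tr_enc[[i]]$x)$y
          fr <- discriminator_forward(dp, disc_cfg, tr_enc[[i]]$t,
                                      keep_cache = TRUE)
          gr <- discriminator_backward(dp, disc_cfg, fr$cache,
                                       2 * (fr$y - 1))$grads
          ff <- discriminator_forward(dp, disc_cfg, fake, keep_cache = TRUE)
          gf <- discriminator_backward(dp, disc_cfg, ff$cache,
                                       2 * ff$y)$grads
          dp <- adam_step(d_opt, dp, Map(`+`, gr, gf))
          d_loss <- (fr$y - 1)^2 + ff$y^2
        }
      }
      history[[it]] <- data.frame(iteration = it,
                                  gen_loss = mean(g_losses),
                                  disc_loss = d_loss)
      if (it %% train_cfg$val_every == 0) {
        mae <- .val_mae(gp, gen_cfg, val_enc)
        val_iters <- c(val_iters, it); val_maes <- c(val_maes, mae)
        if (mae < best_mae) { best <- gp; best_mae <- mae; best_iter <- it }
        if (verbose)
          message(sprintf("iter %d: val MAE %.5f (best %.5f @ %d)",
                          it, mae, best_mae, best_iter))
      }
    }
    structure(list(
      params = best,
      gen_cfg = gen_cfg, disc_cfg = disc_cfg, train_cfg = train_cfg,
      history = list(iterations = do.call(rbind, history),
                     validation = data.frame(iteration = val_iters,
                                             val_mae = val_maes),
                     selected_iteration = best_iter,
                     selected_val_mae = best_mae,
                     initial_val_mae = mae0)),
      class = "brightfield_gan")
  })
}

#' @export
print.brightfield_gan <- function(x, ...) {
  h <- x$history
  cat("Cross-modality bright-field GAN\n")
  cat(sprintf("  generator: depth %d, base %d channels, %d residual blocks/level\n",
              x$gen_cfg$depth, x$gen_cfg$base_channels,
              x$gen_cfg$residual_blocks))
  cat(sprintf("  trained %d iterations (adversarial weight %g)\n",
              max(h$iterations$iteration), x$train_cfg$adversarial_weight))
  cat(sprintf("  selected checkpoint: iteration %d, validation MAE %.5f (initial %.5f)\n",
              h$selected_iteration, h$selected_val_mae, h$initial_val_mae))
  invisible(x)
}

#' @export
summary.brightfield_gan <- function(object, ...) {
  h <- object$history
  n_par <- sum(vapply(object$params, length, numeric(1)))
  cat("Cross-modality bright-field GAN\n")
  cat(sprintf("  parameters: %d\n", n_par))
  cat(sprintf("  validation MAE: initial %.5f -> best %.5f (%.1f%% drop) at iteration %d\n",
              h$initial_val_mae, h$selected_val_mae,
              100 * (1 - h$selected_val_mae / h$initial_val_mae),
              h$selected_iteration))
  print(utils::tail(h$validation, 5))
  invisible(object)
}

#' @export
plot.brightfield_gan <- function(x, ...) {
  h <- x$history
  graphics::plot(h$validation$iteration, h$validation$val_mae, type = "b",
                 xlab = "iteration", ylab = "validation MAE",
                 main = "Training history", ...)
  graphics::abline(v = h$selected_iteration, lty = 2)
  invisible(x)
}

# edge-replicate an (H, W, C) array up to target dims
.pad_to <- function(x, H, W) {
  d <- dim(x)
  if (d[1] < H) x <- x[c(seq_len(d[1]), rep(d[1], H - d[1])), , , drop = FALSE]
  if (d[2] < W) x <- x[, c(seq_len(d[2]), rep(d[2], W - d[2])), , drop = FALSE]
  x
}

#' Infer a bright-field image from one backpropagated plane
#'
#' Splits the plane into overlapping tiles, normalizes each exactly as in
#' training (per-tile z-score of the Re/Im channels), runs the generator and
#' blends tile outputs with linear feathering in the overlaps.
#'
#' @param model a trained [train_brightfield_gan()] object.
#' @param plane a [complex_field()] or complex matrix.
#' @param tile tile side in px (default 256).
#' @param overlap tile overlap in px (default 32).
#' @return an (H, W, 3) RGB array in [0, 1] with the input's spatial dims.
#' @export
infer <- function(model, plane, tile = 256, overlap = 32) {
  stopifnot(inherits(model, "brightfield_gan"))
  v <- if (inherits(plane, "complex_field")) plane$values else plane
  depth <- model$gen_cfg$depth
  if (tile < 2^depth) stop("tile smaller than 2^depth", call. = FALSE)
  H <- nrow(v); W <- ncol(v)
  tile_h <- min(tile, H); tile_w <- min(tile, W)
  # generator needs dims divisible by 2^depth; round tiles up and pad
  tile_h <- min(ceiling(tile_h / 2^depth) * 2^depth, ceiling(H / 2^depth) * 2^depth)
  tile_w <- min(ceiling(tile_w / 2^depth) * 2^depth, ceiling(W / 2^depth) * 2^depth)
  starts <- function(total, tl) {
    if (tl >= total) return(1L)
    s <- seq(1L, total - tl + 1L, by = tl - overlap)
    if (s[length(s)] + tl - 1L < total) s <- c(s, total - tl + 1L)
    s
  }
  rs <- starts(H, tile_h); cs <- starts(W, tile_w)
  acc <- array(0, c(H, W, 3)); wacc <- matrix(0, H, W)
  feather <- function(n, tl) {
    w <- rep(1, tl)
    if (overlap > 0 && tl < n) {
      ramp <- seq(1 / (overlap + 1), 1 - 1 / (overlap + 1),
                  length.out = overlap)
      w[seq_len(overlap)] <- ramp
      w[tl + 1 - seq_len(overlap)] <- ramp
    }
    w
  }
  for (r0 in rs) for (c0 in cs) {
    r1 <- min(r0 + tile_h - 1L, H); c1 <- min(c0 + tile_w - 1L, W)
    sub <- v[r0:r1, c0:c1, drop = FALSE]
    enc <- encode_input(sub)
    x <- .pad_to(enc$x, tile_h, tile_w)
    y <- generator_forward(model$params, model$gen_cfg, x)$y
    y <- y[seq_len(r1 - r0 + 1L), seq_len(c1 - c0 + 1L), , drop = FALSE]
    wr <- feather(H, r1 - r0 + 1L); wc <- feather(W, c1 - c0 + 1L)
    wt <- outer(wr, wc)
    for (ch in 1:3) acc[r0:r1, c0:c1, ch] <-
      acc[r0:r1, c0:c1, ch] + y[, , ch] * wt
    wacc[r0:r1, c0:c1] <- wacc[r0:r1, c0:c1] + wt
  }
  for (ch in 1:3) acc[, , ch] <- acc[, , ch] / wacc
  pmin(pmax(acc, 0), 1)
}

#' Infer a full virtual bright-field z-stack from a backpropagation stack
#'
#' Plane-wise [infer()]: the single-snapshot hologram, backpropagated to a
#' range of heights and pushed through the generator, yields a virtual
#' incoherent z-stack.
#'
#' @inheritParams infer
#' @param stack a "backpropagation" [field_stack()].
#' @return a [field_stack()] of modality "network_output" with the same
#'   `z_list`.
#' @export
infer_stack <- function(model, stack, tile = 256, overlap = 32) {
  stopifnot(inherits(stack, "field_stack"))
  planes <- lapply(stack$planes, function(p) infer(model, p, tile, overlap))
  field_stack(planes, stack$z_list, stack$pitch, "network_output")
}

#' @export
#' @rdname infer
#' @param object a `brightfield_gan` model.
#' @param newdata a [complex_field()], complex matrix, or [field_stack()].
#' @param ... passed to [infer()] / [infer_stack()].
predict.brightfield_gan <- function(object, newdata, ...) {
  if (inherits(newdata, "field_stack")) infer_stack(object, newdata, ...)
  else infer(object, newdata, ...)
}
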