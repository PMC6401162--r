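test_that("dihedral augmentation counts, distinctness and involution hold", {
  ds <- tiny_dataset()
  pairs <- ds$train[1:6]
  expect_identical(augment_pairs(pairs, factor = 1), pairs)
  aug <- augment_pairs(pairs, factor = 5, seed = 2)
  expect_length(aug, 30)
  ks <- vapply(aug, `[[`, numeric(1), "transform")
  for (g in split(ks, rep(1:6, each = 5)))
    expect_length(unique(g), 5)
  # input and target receive the same transform
  k_rot2 <- holobright:::.dihedral(pairs[[1]]$input, 2)
  expect_identical(holobright:::.dihedral(k_rot2, 2), pairs[[1]]$input)
  expect_error(augment_pairs(pairs, factor = 9), "between 1 and 8")
})

test_that("generator and discriminator gradients match finite differences", {
  gcfg <- generator_config(depth = 2, base_channels = 4,
                           residual_blocks = 1)
  gp <- with_seed(5, holobright:::generator_init(gcfg))
  x <- with_seed(6, array(rnorm(16 * 16 * 2), c(16, 16, 2)))
  tgt <- with_seed(7, array(runif(16 * 16 * 3), c(16, 16, 3)))
  fw <- holobright:::generator_forward(gp, gcfg, x, keep_cache = TRUE)
  bw <- holobright:::generator_backward(gp, gcfg, fw$cache,
                                        sign(fw$y - tgt) / length(tgt))
  loss <- function(p) mean(abs(holobright:::generator_forward(p, gcfg,
                                                              x)$y - tgt))
  eps <- 1e-6
  for (nm in c("stem.W", "enc0_rb1_c1.W", "down1.W", "bott_rb1_c2.W",
               "up0.W", "fuse1.W", "head.b")) {
    i <- with_seed(nchar(nm), sample(length(gp[[nm]]), 1))
    p2 <- gp
    p2[[nm]][i] <- p2[[nm]][i] + eps; lp <- loss(p2)
    p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; lm <- loss(p2)
    expect_equal(bw$grads[[nm]][i], (lp - lm) / (2 * eps),
                 tolerance = 1e-4, label = nm)
  }
  dcfg <- discriminator_config(base_channels = 4)
  dp <- with_seed(8, holobright:::discriminator_init(dcfg))
  xi <- with_seed(9, array(runif(64 * 64 * 3), c(64, 64, 3)))
  dfw <- holobright:::discriminator_forward(dp, dcfg, xi, keep_cache = TRUE)
  dbw <- holobright:::discriminator_backward(dp, dcfg, dfw$cache,
                                             2 * (dfw$y - 1))
  dloss <- function(p) (holobright:::discriminator_forward(p, dcfg,
                                                           xi)$y - 1)^2
  for (nm in c("d1.W", "d4.b", "fc1.W", "fc2.W")) {
    i <- with_seed(nchar(nm) + 1, sample(length(dp[[nm]]), 1))
    p2 <- dp
    p2[[nm]][i] <- p2[[nm]][i] + eps; lp <- dloss(p2)
    p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; lm <- dloss(p2)
    expect_equal(dbw$grads[[nm]][i], (lp - lm) / (2 * eps),
                 tolerance = 1e-4, label = nm)
  }
})

test_that("smoke training reduces validation MAE and selects the argmin", {
  ds <- tiny_dataset()
  tr <- ds$train[seq_len(min(16, length(ds$train)))]
  va <- ds$val[seq_len(min(6, length(ds$val)))]
  m <- train_brightfield_gan(tr, va, small_gen_cfg(), small_disc_cfg(),
                             training_config(max_iterations = 60,
                                             val_every = 20,
                                             adversarial_weight = 0,
                                             seed = 1))
  h <- m$history
  expect_lt(h$selected_val_mae, h$initial_val_mae)
  expect_equal(h$selected_val_mae, min(h$validation$val_mae))
  expect_equal(h$validation$val_mae[h$validation$iteration ==
                                      h$selected_iteration],
               h$selected_val_mae)
  # determinism: same seed, same selected MAE
  m2 <- train_brightfield_gan(tr, va, small_gen_cfg(), small_disc_cfg(),
                              training_config(max_iterations = 60,
                                              val_every = 20,
                                              adversarial_weight = 0,
                                              seed = 1))
  expect_identical(m$history$selected_val_mae,
                   m2$history$selected_val_mae)
  expect_error(train_brightfield_gan(list(), va), "nonempty")
})

test_that("tiled inference blends consistently and respects contracts", {
  ds <- tiny_dataset()
  tr <- ds$train[seq_len(min(16, length(ds$train)))]
  va <- ds$val[seq_len(min(4, length(ds$val)))]
  m <- train_brightfield_gan(tr, va, small_gen_cfg(), small_disc_cfg(),
                             training_config(max_iterations = 30,
                                             val_every = 15,
                                             adversarial_weight = 0,
                                             seed = 2))
  plane <- with_seed(3, {
    base <- matrix(complex(real = rnorm(128^2, 1, 0.1),
                           imaginary = rnorm(128^2, 0, 0.1)), 128)
    holobright:::.gauss_blur(Re(base), 2) +
      1i * holobright:::.gauss_blur(Im(base), 2)
  })
  whole <- infer(m, plane, tile = 128, overlap = 0)
  expect_equal(dim(whole), c(128, 128, 3))
  expect_true(all(whole >= 0 & whole <= 1))
  tiled <- infer(m, plane, tile = 64, overlap = 16)
  expect_equal(dim(tiled), c(128, 128, 3))
  expect_lt(holobright:::rms(tiled - whole), 0.02)
  # constant input gives a spatially constant interior
  const <- matrix(1 + 0i, 64, 64)
  yc <- infer(m, const, tile = 64)
  # approximately constant away from zero-padding border effects (the
  # receptive field spans much of a 64-px tile, so exact constancy is
  # limited to numerical leakage, not structure)
  inner <- yc[25:40, 25:40, ]
  expect_lt(max(abs(sweep(inner, 3, apply(inner, 3, mean)))), 1e-3)
  expect_error(infer(m, plane, tile = 2), "2\\^depth")
  # stack inference preserves the axis
  st <- field_stack(list(plane, plane), c(0, 0.5), 1.12 / 3,
                    "backpropagation")
  out <- infer_stack(m, st, tile = 64, overlap = 16)
  expect_equal(out$z_list, st$z_list)
  expect_length(out$planes, 2)
  expect_equal(out$modality, "network_output")
})
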