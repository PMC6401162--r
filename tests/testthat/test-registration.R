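test_that("identical images register to the identity transform", {
  img <- textured_image(128, 3)
  tf <- estimate_rigid(img, img)
  expect_lt(abs(tf$dx), 0.05)
  expect_lt(abs(tf$dy), 0.05)
  expect_lt(abs(tf$theta), 0.05)
})

test_that("known rigid transforms are recovered on seeded cases", {
  img <- textured_image(128, 3)
  errs <- t(vapply(1:20, function(i) {
    tf_true <- with_seed(100 + i,
      rigid_transform(runif(1, -4, 4), runif(1, -4, 4), runif(1, -1.5, 1.5)))
    mov <- warp_rigid(img, rigid_transform(-tf_true$dx, -tf_true$dy, 0))
    mov <- warp_rigid(mov, rigid_transform(0, 0, -tf_true$theta))
    tf <- estimate_rigid(mov, img, theta_range = 3, theta_step = 0.1)
    c(abs(tf$dx - tf_true$dx), abs(tf$dy - tf_true$dy),
      abs(tf$theta - tf_true$theta))
  }, numeric(3)))
  expect_lt(max(errs[, 1:2]), 0.25)
  expect_lt(max(errs[, 3]), 0.2)
})

test_that("registration is composition-consistent and rejects pure noise", {
  img <- textured_image(96, 5)
  mov <- warp_rigid(img, rigid_transform(2.4, -1.2, 0.8))
  ab <- estimate_rigid(mov, img, theta_range = 2)
  ba <- estimate_rigid(img, mov, theta_range = 2)
  expect_lt(abs(ab$dx + ba$dx), 0.3)
  expect_lt(abs(ab$dy + ba$dy), 0.3)
  expect_lt(abs(ab$theta + ba$theta), 0.25)
  n1 <- with_seed(1, matrix(rnorm(96^2), 96))
  n2 <- with_seed(2, matrix(rnorm(96^2), 96))
  expect_error(estimate_rigid(n1, n2), "low-confidence")
  expect_error(estimate_rigid(n1, matrix(1, 96, 96)), "non-constant")
})

test_that("axial zero registration recovers a known offset", {
  ext <- 96 * 1.12
  z_true <- 503
  ph <- point_phantom(ext / 2, ext / 2, z_true, radius = 0.8, extent = ext)
  holo <- simulate_inline_hologram(ph, optical_geometry(), c(96, 96),
                                   noise_sd = 0.005, seed = 6)
  # bright-field stack whose own z axis places the bead at +7 um
  zl <- seq(-10, 24, by = 0.5)
  bf <- render_brightfield_stack(ph, z_true - 7 + zl, c(96, 96), 1.12)
  bf$z_list <- zl
  off <- axial_zero_register(holo, bf, 450, 550, coarse_step = 10, tol = 0.1)
  expect_lt(abs(off - (7 - z_true)), 1)
  # aligned pair: offset within one axial step of -z_true
  bf2 <- render_brightfield_stack(ph, z_true + seq(-10, 10, 0.5), c(96, 96),
                                  1.12)
  bf2$z_list <- seq(-10, 10, 0.5)
  off2 <- axial_zero_register(holo, bf2, 450, 550, coarse_step = 10,
                              tol = 0.1)
  expect_lt(abs(off2 + z_true), 0.5 + 0.5)
})

test_that("registered patch pairs tile the planes as counted", {
  ext <- 128 * 1.12
  ph <- generate_phantom(4, ext, c(498, 502), radius_dist = c(1, 0),
                         min_separation = 15, seed = 9)
  holo <- simulate_inline_hologram(ph, optical_geometry(), c(128, 128),
                                   noise_sd = 0, seed = 9)
  z_ref <- mean(vapply(ph$scatterers, `[[`, numeric(1), "z"))
  zl <- z_ref + c(-2, 0, 2)
  bp <- backpropagate_hologram(holo, zl, pad_factor = 1)
  bf <- render_brightfield_stack(ph, zl, c(128, 128), 1.12)
  bf$z_list <- bp$z_list   # identical axes by construction
  pairs <- make_registered_pairs(bp, bf, patch = 64, stride = 32,
                                 register = FALSE)
  expect_length(pairs, 3 * 9)   # (128-64)/32+1 = 3 starts per axis
  expect_true(all(vapply(pairs, function(p) is.complex(p$input), logical(1))))
  expect_equal(dim(pairs[[1]]$target), c(64, 64, 3))
  expect_error(make_registered_pairs(bp, bf, patch = 256, stride = 32),
               "patch larger")
  # a known shift applied to the bright-field planes is undone by
  # registration: patch contents match the aligned case
  bf_shift <- bf
  for (k in seq_along(bf$planes)) {
    pl <- bf$planes[[k]]
    for (ch in 1:3) pl[, , ch] <- warp_rigid(pl[, , ch],
                                             rigid_transform(6, -4, 0))
    bf_shift$planes[[k]] <- pl
  }
  reg_pairs <- make_registered_pairs(bp, bf_shift, patch = 64, stride = 32,
                                     register = TRUE, theta_range = 1)
  ref_by_key <- setNames(pairs, vapply(pairs, function(p)
    sprintf("%g_%d_%d", p$z, p$row, p$col), character(1)))
  errs <- vapply(reg_pairs, function(p) {
    key <- sprintf("%g_%d_%d", p$z, p$row, p$col)
    holobright:::rms(p$target - ref_by_key[[key]]$target)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.02)
})
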