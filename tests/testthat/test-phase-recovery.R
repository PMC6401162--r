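test_that("support estimation covers a dark disk with its dilation margin", {
  amp <- matrix(1, 128, 128)
  cov <- holobright:::disk_coverage(128, 128, 1, 64, 64, 8)
  amp <- amp - 0.8 * cov
  sup <- estimate_support(amp, k = 1.5, dilation = 6)
  area_disk <- sum(cov > 0.5)
  area_dilated <- pi * (8 + 6)^2
  expect_gte(sum(sup$mask), area_disk)
  expect_lt(sum(sup$mask), 1.25 * area_dilated)
  # the disk itself is fully inside the mask
  expect_true(all(sup$mask[cov > 0.5]))
  expect_error(estimate_support(matrix(1, 32, 32)), "empty support")
  # k = 0 flags every off-mean pixel (before dilation)
  sup0 <- estimate_support(amp, k = 0, dilation = 0)
  expect_true(all(sup0$mask[amp != mean(amp)]))
})

test_that("iterations = 0 reproduces plain backpropagation exactly", {
  ext <- 96 * 1.12
  ph <- point_phantom(ext / 2, ext / 2, 500, radius = 3, absorption = 0.9,
                      extent = ext)
  holo <- simulate_inline_hologram(ph, optical_geometry(), c(96, 96),
                                   noise_sd = 0.005, seed = 1)
  bp <- backpropagate_hologram(holo, 500, pad_factor = 1)
  sup <- estimate_support(Mod(bp$planes[[1]]), k = 2, dilation = 6)
  rec0 <- iterative_phase_recovery(holo, 500, sup, iterations = 0)
  expect_equal(rec0$values, bp$planes[[1]], tolerance = 1e-12)
})

test_that("phase recovery suppresses the twin image and improves CNR", {
  n <- 128; ext <- n * 1.12
  ph <- point_phantom(ext / 2, ext / 2, 500, radius = 4, absorption = 0.9,
                      extent = ext)
  holo <- simulate_inline_hologram(ph, optical_geometry(), c(n, n),
                                   noise_sd = 0.005, seed = 2)
  bp <- backpropagate_hologram(holo, 500, pad_factor = 1)
  amp0 <- Mod(bp$planes[[1]])
  sup <- estimate_support(amp0, k = 2, dilation = 6)
  rec <- iterative_phase_recovery(holo, 500, sup, iterations = 100)
  D <- holobright:::disk_coverage(n, n, 1.12, ext / 2, ext / 2, 4) > 0
  true_sup <- EBImage::dilate(matrix(as.numeric(D), n),
                              EBImage::makeBrush(13, "disc")) > 0.5
  e0 <- twin_image_energy(bp$planes[[1]], true_sup)
  e1 <- twin_image_energy(rec$values, true_sup)
  expect_lt(e1, 0.5 * e0)
  bg <- !(EBImage::dilate(matrix(as.numeric(D), n),
                          EBImage::makeBrush(41, "disc")) > 0.5)
  cnr0 <- compute_cnr(amp0, D, bg)$cnr
  cnr1 <- compute_cnr(Mod(rec$values), D, bg)$cnr
  expect_gt(cnr1, cnr0)
})

test_that("twin-image energy trend is non-increasing in smoothed windows", {
  n <- 96; ext <- n * 1.12
  ph <- point_phantom(ext / 2, ext / 2, 500, radius = 3, absorption = 0.9,
                      extent = ext)
  holo <- simulate_inline_hologram(ph, optical_geometry(), c(n, n),
                                   noise_sd = 0.005, seed = 3)
  bp <- backpropagate_hologram(holo, 500, pad_factor = 1)
  sup <- estimate_support(Mod(bp$planes[[1]]), k = 2, dilation = 6)
  D <- holobright:::disk_coverage(n, n, 1.12, ext / 2, ext / 2, 3) > 0
  true_sup <- EBImage::dilate(matrix(as.numeric(D), n),
                              EBImage::makeBrush(13, "disc")) > 0.5
  energies <- vapply(seq(0, 50, by = 10), function(it)
    twin_image_energy(iterative_phase_recovery(holo, 500, sup,
                                               iterations = it)$values,
                      true_sup), numeric(1))
  expect_true(all(diff(energies) <= 1e-8))
})

test_that("final sensor amplitude equals the measurement by construction", {
  # the last constraint step replaces amplitude with sqrt(intensity); verify
  # by forward-propagating the recovered object field back to the sensor and
  # checking it reproduces the recovered phase under the measured amplitude
  n <- 64; ext <- n * 1.12
  ph <- point_phantom(ext / 2, ext / 2, 500, radius = 3, absorption = 0.9,
                      extent = ext)
  holo <- simulate_inline_hologram(ph, optical_geometry(), c(n, n),
                                   noise_sd = 0, seed = 1)
  bp <- backpropagate_hologram(holo, 500, pad_factor = 1)
  sup <- estimate_support(Mod(bp$planes[[1]]), k = 2, dilation = 4)
  rec <- iterative_phase_recovery(holo, 500, sup, iterations = 3)
  back_at_sensor <- propagate(rec, -500)$values
  resynth <- sqrt(holo$intensity) * exp(1i * Arg(back_at_sensor))
  obj_again <- propagate(complex_field(resynth, 1.12, 0.85, 0), 500)$values
  expect_equal(obj_again, rec$values, tolerance = 1e-10)
})
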