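test_that("angular spectrum kernel satisfies its closed-form identities", {
  shp <- c(32, 48)
  H0 <- angular_spectrum_kernel(shp, 1.12, 0.85, 0)
  prop <- Mod(H0) > 0
  expect_true(all(abs(H0[prop] - 1) < 1e-12))
  Hp <- angular_spectrum_kernel(shp, 1.12, 0.85, 137)
  Hm <- angular_spectrum_kernel(shp, 1.12, 0.85, -137)
  expect_lt(max(Mod(Hp[prop] * Hm[prop] - 1)), 1e-10)
  # zero-frequency element is the plane-wave phase
  expect_equal(Hp[1, 1], exp(2i * pi * 137 / 0.85), tolerance = 1e-12)
  # evanescent region is exactly zero
  fy <- holobright:::fft_freq(shp[1], 1.12)
  fx <- holobright:::fft_freq(shp[2], 1.12)
  ev <- outer(fy^2, fx^2, `+`) > 1 / 0.85^2
  if (any(ev)) expect_true(all(Hp[ev] == 0))
  expect_error(angular_spectrum_kernel(shp, -1, 0.85, 10), "pitch")
  expect_error(angular_spectrum_kernel(shp, 1.12, 0, 10), "wavelength")
})

test_that("propagation is unitary and invertible for band-limited fields", {
  u <- with_seed(1, matrix(complex(real = rnorm(64^2),
                                   imaginary = rnorm(64^2)), 64))
  U <- stats::fft(u)
  f <- holobright:::fft_freq(64, 1.12)
  U[outer(f^2, f^2, `+`) > (0.3 / 1.12)^2] <- 0
  u <- stats::fft(U, inverse = TRUE) / length(U)
  fld <- complex_field(u, 1.12, 0.85, 0)
  same <- propagate(fld, 0)
  expect_identical(same$values, u)
  rt <- propagate(propagate(fld, 211), -211)
  expect_lt(max(Mod(rt$values - u)) / max(Mod(u)), 1e-10)
  expect_equal(rt$z, 0)
  fw <- propagate(fld, 350)
  expect_equal(sum(Mod(fw$values)^2), sum(Mod(u)^2), tolerance = 1e-10)
})

test_that("angular spectrum agrees with the Rayleigh-Sommerfeld summation oracle", {
  # band-limited (Gaussian-apodized) aperture: the comparison is meaningful
  # only below the sensor Nyquist frequency
  n <- 64; pitch <- 1.12; lam <- 0.85; z <- 200
  r2 <- (row(matrix(0, n, n)) - n / 2 - 0.5)^2 +
        (col(matrix(0, n, n)) - n / 2 - 0.5)^2
  u0 <- exp(-r2 / (2 * 2.5^2)) + 0i
  as_field <- propagate(complex_field(u0, pitch, lam, 0), z)$values
  rs <- rs_oracle(u0, pitch, lam, z)
  cen <- (n / 2 - 16):(n / 2 + 15)
  rel <- max(Mod(as_field[cen, cen] - rs[cen, cen])) / max(Mod(rs[cen, cen]))
  expect_lt(rel, 1e-3)
})

test_that("hologram fringe radius scales as sqrt(lambda z)", {
  # first dark ring radius of a point-like scatterer hologram at two z
  first_min_radius <- function(z) {
    n <- 512; pitch <- 1.12
    ext <- n * pitch
    ph <- point_phantom(ext / 2, ext / 2, z, radius = 0.6, absorption = 1,
                        extent = ext)
    holo <- simulate_inline_hologram(ph, optical_geometry(), c(n, n),
                                     noise_sd = 0)
    prof <- holo$intensity[n / 2, (n / 2):(n / 2 + 120)]
    # first local minimum beyond the central max
    i <- which(diff(sign(diff(prof))) > 0)[1] + 1
    (i - 1) * pitch
  }
  r1 <- first_min_radius(400)
  r2 <- first_min_radius(625)
  expect_equal(r2 / r1, sqrt(625 / 400), tolerance = 0.02)
})

test_that("backpropagate_hologram honors padding and refocuses a bead", {
  ext <- 96 * 1.12
  uni <- hologram_frame(matrix(1, 64, 64), preprocessed = TRUE)
  st <- backpropagate_hologram(uni, c(400, 500), pad_factor = 1)
  expect_equal(dim(st$planes[[1]]), c(64, 64))
  for (p in st$planes) expect_lt(max(abs(Mod(p) - 1)), 1e-10)
  st3 <- backpropagate_hologram(uni, 500, pad_factor = 3)
  expect_equal(dim(st3$planes[[1]]), c(192, 192))
  expect_equal(st3$pitch, 1.12 / 3)
  expect_error(backpropagate_hologram(uni, 500, pad_factor = 0),
               "pad_factor")
  ph <- point_phantom(ext / 2, ext / 2, 500, radius = 0.5, extent = ext)
  holo <- simulate_inline_hologram(ph, optical_geometry(), c(96, 96),
                                   noise_sd = 0.01, seed = 3)
  zs <- seq(490, 510, by = 0.5)
  stack <- backpropagate_hologram(holo, zs, pad_factor = 3)
  scores <- vapply(stack$planes,
                   function(p) tamura_of_gradient(Mod(p)), numeric(1))
  expect_lt(abs(zs[which.max(scores)] - 500), 1)
})

test_that("the inline hologram forward model matches the diffraction oracle", {
  # opaque disk at z = 500 um on a grid satisfying the kernel sampling bound
  n <- 384; pitch <- 1.12; lam <- 0.85; z <- 500
  ext <- n * pitch
  ph <- point_phantom(ext / 2, ext / 2, z, radius = 2.5, absorption = 1,
                      extent = ext)
  holo <- simulate_inline_hologram(ph, optical_geometry(), c(n, n),
                                   noise_sd = 0)
  D <- holobright:::disk_coverage(n, n, pitch, ext / 2, ext / 2, 2.5)
  u_rs <- exp(2i * pi * z / lam) - rs_oracle(D + 0i, pitch, lam, z)
  I_rs <- Mod(u_rs)^2
  I_rs <- I_rs / mean(I_rs)
  cen <- (n / 2 - 32):(n / 2 + 32)
  expect_lt(max(abs(holo$intensity[cen, cen] - I_rs[cen, cen])) / max(I_rs),
            1e-3)
})

test_that("multi-plane holograms compose as sequential single-plane models", {
  n <- 96; pitch <- 1.12; lam <- 0.85
  ext <- n * pitch
  s1 <- scatterer(ext / 2 - 10, ext / 2, 520, radius = 1, absorption = 0.8)
  s2 <- scatterer(ext / 2 + 12, ext / 2 + 4, 480, radius = 1.5,
                  absorption = 0.6, phase_shift = 0.4)
  ph <- multi_phantom(list(s1, s2), ext)
  holo <- simulate_inline_hologram(ph, optical_geometry(), c(n, n),
                                   noise_sd = 0)
  # manual composition: transmittance at 520, propagate 40, transmittance at
  # 480, propagate 480 to the sensor
  t_of <- function(s) {
    cov <- holobright:::disk_coverage(n, n, pitch, s$x, s$y, s$radius)
    1 + cov * ((1 - s$absorption) * exp(1i * s$phase_shift) - 1)
  }
  u <- matrix(1 + 0i, n, n) * t_of(s1)
  u <- propagate(complex_field(u, pitch, lam, 520), -40)$values * t_of(s2)
  u <- propagate(complex_field(u, pitch, lam, 480), -480)$values
  I <- Mod(u)^2
  I <- I / mean(I)
  expect_equal(holo$intensity, I, tolerance = 1e-12)
})

test_that("degenerate and invalid phantoms are handled", {
  empty <- generate_phantom(0, 100, c(490, 510), seed = 1)
  holo <- simulate_inline_hologram(empty, optical_geometry(), c(32, 32),
                                   noise_sd = 0)
  expect_true(all(abs(holo$intensity - 1) < 1e-12))
  out <- point_phantom(1000, 50, 500, extent = 96 * 1.12)
  expect_error(simulate_inline_hologram(out, optical_geometry(), c(96, 96)),
               "outside")
})
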