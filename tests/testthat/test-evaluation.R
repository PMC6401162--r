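test_that("metric identities and closed forms hold", {
  img <- textured_image(64, 11) + 2
  m <- compute_metrics(img, img)
  expect_equal(m$rmse, 0)
  expect_equal(m$ssim, 1, tolerance = 1e-12)
  expect_equal(m$uiqi, 1, tolerance = 1e-12)
  # constant offset: UIQI from the closed-form moments of the fixture
  cshift <- 0.5
  test <- img + cshift
  mx <- mean(test); my <- mean(img)
  v <- mean((img - my)^2)                       # sigma^2 equal for both
  q_expected <- 4 * v * mx * my / ((2 * v) * (mx^2 + my^2))
  m2 <- compute_metrics(test, img)
  expect_equal(m2$uiqi, q_expected, tolerance = 1e-12)
  # sign-flipped fluctuations anti-correlate
  flipped <- -(img - mean(img)) + mean(img)
  expect_lt(compute_metrics(flipped, img)$uiqi, 0)
  expect_error(compute_metrics(img, matrix(1, 64, 64)), "constant")
  expect_error(compute_metrics(img[1:32, ], img), "dimensions")
})

test_that("CNR matches constructed moments", {
  fg <- matrix(FALSE, 40, 40); fg[5:14, 5:14] <- TRUE
  bg <- matrix(FALSE, 40, 40); bg[20:39, 1:40] <- TRUE
  img <- matrix(0, 40, 40)
  img[fg] <- 10
  img[bg] <- with_seed(8, rnorm(sum(bg), mean = 2, sd = 0.5))
  cnr <- compute_cnr(img, fg, bg)
  expect_equal(cnr$cnr, 16, tolerance = 0.05 * 16)
  img2 <- img; img2[fg] <- mean(img[bg])
  expect_lt(compute_cnr(img2, fg, bg)$cnr, 0.1)
  img3 <- img; img3[bg] <- 2
  expect_error(compute_cnr(img3, fg, bg), "constant")
  expect_error(compute_cnr(img, fg, fg), "disjoint")
})

test_that("FWHM measurement matches Gaussian and triangle closed forms", {
  xs <- seq(-8, 8, by = 0.1)
  gauss <- exp(-xs^2 / 2)
  expect_equal(measure_fwhm(gauss, 0.1), 2 * sqrt(2 * log(2)),
               tolerance = 0.01)
  tri <- pmax(0, 1 - abs(xs) / 2)      # half-width at half-max = 1, FWHM 2
  expect_equal(measure_fwhm(tri, 0.1), 2, tolerance = 1e-6)
  expect_error(measure_fwhm(seq(0, 1, by = 0.01), 0.01), "boundary")
})

test_that("bead detection localizes isolated beads and enforces isolation", {
  # synthetic 3-D Gaussian blobs in a 64x64x31 stack
  make_stack <- function(centers_px, sig_lat = 2, sig_ax = 3) {
    zs <- 1:31
    planes <- lapply(zs, function(zi) {
      pl <- matrix(0, 64, 64)
      for (cc in centers_px) {
        r2 <- (row(pl) - cc[1])^2 + (col(pl) - cc[2])^2
        pl <- pl + exp(-r2 / (2 * sig_lat^2)) *
          exp(-(zi - cc[3])^2 / (2 * sig_ax^2))
      }
      1 - 0.8 * pmin(pl, 1)        # dark blobs on white
    })
    field_stack(planes, zs, 1, "brightfield_gt")
  }
  st <- make_stack(list(c(16, 16, 10), c(48, 20, 16), c(30, 50, 22)))
  det <- detect_beads(st, min_separation = 8)
  expect_equal(nrow(det), 3)
  truth <- rbind(c(15.5, 15.5, 10), c(19.5, 47.5, 16), c(49.5, 29.5, 22))
  ord <- order(det$z)
  for (i in 1:3) {
    expect_lt(abs(det$x[ord[i]] - truth[i, 1]), 0.5)
    expect_lt(abs(det$y[ord[i]] - truth[i, 2]), 0.5)
    expect_lt(abs(det$z[ord[i]] - truth[i, 3]), 0.5)
  }
  # two beads closer than min_separation are both excluded
  st2 <- make_stack(list(c(30, 30, 15), c(30, 36, 15)))
  expect_equal(nrow(detect_beads(st2, min_separation = 10)), 0)
  flat <- field_stack(replicate(5, matrix(1, 32, 32), simplify = FALSE),
                      1:5, 1, "brightfield_gt")
  expect_equal(nrow(detect_beads(flat, min_separation = 5)), 0)
})

test_that("bead PSF statistics recover known Gaussian widths", {
  # one 3-D Gaussian blob: sigma_lat = 0.8 um, sigma_ax = 4 um
  pitch <- 0.25; dz <- 0.5
  zs <- seq(-15, 15, by = dz)
  planes <- lapply(zs, function(z) {
    pl <- matrix(0, 96, 96)
    r2 <- ((row(pl) - 48.5) * pitch)^2 + ((col(pl) - 48.5) * pitch)^2
    1 - 0.7 * exp(-r2 / (2 * 0.8^2)) * exp(-z^2 / (2 * 4^2))
  })
  st <- field_stack(planes, zs, pitch, "brightfield_gt")
  det <- detect_beads(st, min_separation = 5)
  expect_equal(nrow(det), 1)
  stats <- bead_psf_stats(st, det)
  expect_equal(stats$median_lateral, 2.3548 * 0.8, tolerance = 0.02)
  expect_equal(stats$median_axial, 2.3548 * 4, tolerance = 0.02)
  expect_error(bead_psf_stats(st, det[0, ]), "no centroids")
})

test_that("PSF width recovery works across a seeded blob population", {
  pitch <- 0.25
  zs <- seq(-6, 6, by = 0.5)
  sig_true <- with_seed(21, runif(30, 0.6, 1.1))
  widths <- vapply(sig_true, function(s) {
    planes <- lapply(zs, function(z) {
      pl <- matrix(0, 48, 48)
      r2 <- ((row(pl) - 24.5) * pitch)^2 + ((col(pl) - 24.5) * pitch)^2
      1 - 0.7 * exp(-r2 / (2 * s^2)) * exp(-z^2 / (2 * 2^2))
    })
    st <- field_stack(planes, zs, pitch, "brightfield_gt")
    det <- detect_beads(st, min_separation = 5)
    bead_psf_stats(st, det)$median_lateral
  }, numeric(1))
  expect_equal(stats::median(widths), 2.3548 * stats::median(sig_true),
               tolerance = 0.03)
  # permutation stability of the medians
  st_perm <- sample(widths)
  expect_identical(stats::median(st_perm), stats::median(widths))
})
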