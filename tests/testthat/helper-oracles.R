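# Independent oracles and shared fixtures, kept free of the implementation
# paths they check.

# Direct first-Rayleigh-Sommerfeld diffraction summation: brute-force
# point-by-point integral, O(N^2 * M) — only for tiny grids.
rs_oracle <- function(u0, pitch, wavelength, z) {
  k <- 2 * pi / wavelength
  src <- which(Mod(u0) > 1e-12, arr.ind = TRUE)
  out <- matrix(0 + 0i, nrow(u0), ncol(u0))
  xs <- (col(out) - 0.5) * pitch
  ys <- (row(out) - 0.5) * pitch
  for (s in seq_len(nrow(src))) {
    sy <- (src[s, 1] - 0.5) * pitch
    sx <- (src[s, 2] - 0.5) * pitch
    r <- sqrt((xs - sx)^2 + (ys - sy)^2 + z^2)
    out <- out + u0[src[s, 1], src[s, 2]] *
      (z / (2 * pi * r)) * (1 / r - 1i * k) * exp(1i * k * r) / r * pitch^2
  }
  out
}

# Radial profile of a disk (radius R, unit height) convolved with a Gaussian
# of width sigma, by direct 2-D numerical quadrature.
disk_gauss_quadrature <- function(r_eval, R, sigma, n_grid = 801) {
  half <- R + 6 * sigma
  xs <- seq(-half, half, length.out = n_grid)
  dx <- xs[2] - xs[1]
  vapply(r_eval, function(r0) {
    gx <- outer(xs^2, (xs - r0)^2, `+`)
    disk <- outer(xs, xs, function(a, b) as.numeric(a^2 + b^2 <= R^2))
    # kernel centered at (r0, 0); disk at origin
    kern <- exp(-gx / (2 * sigma^2)) / (2 * pi * sigma^2)
    sum(disk * t(kern)) * dx^2
  }, numeric(1))
}

# single-scatterer phantom at an explicit position (bypasses sampling)
point_phantom <- function(x, y, z, radius = 0.5, absorption = 0.9,
                          extent = 96 * 1.12, phase_shift = 0,
                          color = c(0.35, 0.35, 0.35)) {
  structure(list(
    scatterers = list(scatterer(x, y, z, radius, absorption, phase_shift,
                                color)),
    lateral_extent = extent, z_range = c(z, z),
    min_separation = 10, seed = 1), class = "phantom")
}

multi_phantom <- function(scatterers, extent) {
  structure(list(scatterers = scatterers, lateral_extent = extent,
                 z_range = range(vapply(scatterers, `[[`, numeric(1), "z")),
                 min_separation = 1, seed = 1), class = "phantom")
}

# smooth random texture for registration tests
textured_image <- function(n, seed, blur_sigma = 1.5) {
  with_seed(seed, {
    m <- matrix(rnorm(n * n), n)
    holobright:::.gauss_blur(m, blur_sigma)
  })
}

# small paired dataset shared by network tests (built once per test run)
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_paired_dataset(
        6, list(dims = c(64, 64), n_beads = 2, z_step = 4, patch = 64,
                stride = 64, pad_factor = 1, noise_sd = 0.005), seed = 1)
    }
    cache
  }
})

small_gen_cfg <- function() generator_config(depth = 2, base_channels = 8,
                                             residual_blocks = 1)
small_disc_cfg <- function() discriminator_config(base_channels = 8)
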