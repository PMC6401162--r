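#' A single spherical scatterer
#'
#' Thin-object description of a micron-scale particle: a disk of given radius
#' that attenuates the field by `absorption` and delays it by `phase_shift`,
#' with an RGB color used only by the incoherent bright-field renderer.
#'
#' @param x,y lateral position in um.
#' @param z axial position in um (height above the sensor).
#' @param radius particle radius in um (> 0).
#' @param absorption amplitude absorption in [0, 1].
#' @param phase_shift phase delay in radians.
#' @param color RGB triplet in [0, 1].
#' @return a `scatterer` list.
#' @export
scatterer <- function(x, y, z, radius = 0.5, absorption = 0.9,
                      phase_shift = 0, color = c(0.35, 0.35, 0.35)) {
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (absorption < 0 || absorption > 1)
    stop("absorption must be in [0, 1]", call. = FALSE)
  if (length(color) != 3 || any(color < 0) || any(color > 1))
    stop("color must be an RGB triplet in [0, 1]", call. = FALSE)
  structure(list(x = x, y = y, z = z, radius = radius,
                 absorption = absorption, phase_shift = phase_shift,
                 color = color), class = "scatterer")
}

#' Generate a sparse 3-D particle phantom
#'
#' Rejection-samples `n` particles uniformly in a box, enforcing a minimum
#' pairwise 3-D center separation (the samples of interest — bioaerosols,
#' beads in a bulk volume — are uniform and relatively sparse). Fully seeded
#' and reproducible.
#'
#' @param n number of particles (>= 0).
#' @param lateral_extent lateral field size in um (square, origin at corner).
#' @param z_range length-2 numeric, axial range in um.
#' @param radius_dist length-2 numeric `(mean, sd)` of the particle radius in
#'   um; draws are truncated at 0.2 um.
#' @param min_separation minimum pairwise 3-D distance in um.
#' @param absorption amplitude absorption assigned to every particle.
#' @param phase_shift phase delay assigned to every particle (radians).
#' @param colors optional list of RGB triplets sampled per particle; default a
#'   neutral dark gray.
#' @param margin lateral margin in um kept free of particle centers.
#' @param seed integer seed.
#' @return an object of class `phantom`.
#' @export
generate_phantom <- function(n, lateral_extent, z_range,
                             radius_dist = c(0.5, 0), min_separation = 10,
                             absorption = 0.9, phase_shift = 0,
                             colors = NULL, margin = 5, seed = 1) {
  stopifnot(n >= 0, length(z_range) == 2, diff(z_range) >= 0)
  sc <- list()
  if (n > 0) {
    sc <- with_seed(seed, {
      pts <- matrix(NA_real_, 0, 3)
      draws <- 0L
      while (nrow(pts) < n) {
        draws <- draws + 1L
        if (draws > 1000 * n)
          stop("infeasible sparsity: rejection sampling exhausted",
               call. = FALSE)
        cand <- c(runif(1, margin, lateral_extent - margin),
                  runif(1, margin, lateral_extent - margin),
                  runif(1, z_range[1], z_range[2]))
        if (nrow(pts) == 0 ||
            min(sqrt(colSums((t(pts) - cand)^2))) >= min_separation)
          pts <- rbind(pts, cand)
      }
      radii <- pmax(rnorm(n, radius_dist[1], radius_dist[2]), 0.2)
      cols <- if (is.null(colors)) replicate(n, c(0.35, 0.35, 0.35),
                                             simplify = FALSE)
              else colors[sample.int(length(colors), n, replace = TRUE)]
      lapply(seq_len(n), function(i)
        scatterer(pts[i, 1], pts[i, 2], pts[i, 3], radii[i],
                  absorption, phase_shift, cols[[i]]))
    })
  }
  structure(list(scatterers = sc, lateral_extent = lateral_extent,
                 z_range = as.numeric(z_range),
                 min_separation = min_separation, seed = seed),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Phantom: %d scatterers, %g um field, z in [%g, %g] um\n",
              length(x$scatterers), x$lateral_extent,
              x$z_range[1], x$z_range[2]))
  invisible(x)
}

# Antialiased coverage mask of a disk on a pixel grid (fraction of each pixel
# covered, via 4x4 subpixel sampling restricted to a bounding box).
disk_coverage <- function(nrow_, ncol_, pitch, cx, cy, radius) {
  cov <- matrix(0, nrow_, ncol_)
  sub <- 4L
  off <- (seq_len(sub) - 0.5) / sub - 0.5
  # pixel centers at (j - 0.5) * pitch horizontally, (i - 0.5) * pitch vertically
  i0 <- max(1L, floor((cy - radius) / pitch - 1) + 1L)
  i1 <- min(nrow_, ceiling((cy + radius) / pitch + 1))
  j0 <- max(1L, floor((cx - radius) / pitch - 1) + 1L)
  j1 <- min(ncol_, ceiling((cx + radius) / pitch + 1))
  if (i0 > i1 || j0 > j1) return(cov)
  for (i in i0:i1) {
    ys <- (i - 0.5 + off) * pitch - cy
    for (j in j0:j1) {
      xs <- (j - 0.5 + off) * pitch - cx
      d2 <- outer(ys^2, xs^2, `+`)
      cov[i, j] <- mean(d2 <= radius^2)
    }
  }
  cov
}

#' Simulate a coherent in-line hologram of a phantom
#'
#' Unit-amplitude plane-wave illumination traverses the object planes in
#' descending z (away from the sensor toward it). Each plane multiplies the
#' field by the thin-object complex transmittance of its scatterers; the field
#' is propagated between consecutive planes and finally to the sensor at
#' z = 0, where the intensity |U|^2 is recorded, optionally with additive
#' Gaussian sensor noise.
#'
#' @param phantom a [generate_phantom()] result.
#' @param geometry an [optical_geometry()]; scatterer heights are absolute, so
#'   `geometry$z2` is only the nominal sample height.
#' @param dims integer (rows, cols) of the sensor grid.
#' @param noise_sd standard deviation of additive intensity noise (default
#'   0.01; 0 disables).
#' @param seed integer seed for the noise draw.
#' @return a [hologram_frame()] with `preprocessed = TRUE` (unit-mean
#'   normalized).
#' @export
simulate_inline_hologram <- function(phantom, geometry = optical_geometry(),
                                     dims = c(128, 128), noise_sd = 0.01,
                                     seed = 1) {
  stopifnot(inherits(phantom, "phantom"))
  pitch <- geometry$pixel_pitch
  lam <- geometry$wavelength / geometry$medium_index
  extent_y <- dims[1] * pitch; extent_x <- dims[2] * pitch
  for (s in phantom$scatterers) {
    if (s$x - s$radius < 0 || s$x + s$radius > extent_x ||
        s$y - s$radius < 0 || s$y + s$radius > extent_y)
      stop("scatterer outside the lateral field of view", call. = FALSE)
    if (s$z <= 0) stop("scatterer must lie above the sensor", call. = FALSE)
  }
  u <- matrix(1 + 0i, dims[1], dims[2])
  zs <- vapply(phantom$scatterers, `[[`, numeric(1), "z")
  if (length(zs) > 0) {
    # group scatterers into planes (identical z within a nanometre)
    ord <- order(-zs)
    z_planes <- unique(round(zs[ord], 3))
    z_cur <- NULL
    for (zp in z_planes) {
      if (!is.null(z_cur)) {
        f <- complex_field(u, pitch, lam, z_cur)
        u <- propagate(f, -(z_cur - zp))$values
      }
      t_plane <- matrix(1 + 0i, dims[1], dims[2])
      for (s in phantom$scatterers[round(zs, 3) == zp]) {
        cov <- disk_coverage(dims[1], dims[2], pitch, s$x, s$y, s$radius)
        t_s <- (1 - s$absorption) * exp(1i * s$phase_shift)
        t_plane <- t_plane * (1 + cov * (t_s - 1))
      }
      u <- u * t_plane
      z_cur <- zp
    }
    f <- complex_field(u, pitch, lam, z_cur)
    u <- propagate(f, -z_cur)$values
  }
  intensity <- Mod(u)^2
  if (noise_sd > 0)
    intensity <- intensity +
      with_seed(seed, matrix(rnorm(length(intensity), 0, noise_sd),
                             dims[1], dims[2]))
  intensity <- pmax(intensity, 0)
  intensity <- intensity / mean(intensity)
  hologram_frame(intensity, geometry, preprocessed = TRUE)
}
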