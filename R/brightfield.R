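#' Parametric incoherent bright-field defocus model
#'
#' A high-NA incoherent microscope renders a particle as a colored absorbing
#' disk whose blur grows with defocus. The blur is modeled as a Gaussian of
#' width sigma(dz) = sigma0 * sqrt(1 + (dz / z_R)^2): diffraction-limited at
#' focus, linear far from focus. Defaults follow a 20x/0.75 NA objective at
#' a 0.55 um center wavelength: sigma0 from the Airy radius
#' 0.61 * lambda / NA (~0.45 um) and z_R from n * lambda / NA^2 (~0.98 um).
#'
#' @param NA_ numerical aperture in (0, 1).
#' @param lambda_center center wavelength in um.
#' @param sigma0 in-focus blur sigma in um; default `0.61 * lambda / NA_`.
#' @param z_R axial defocus scale in um; default `lambda / NA_^2` (n = 1).
#' @return an object of class `brightfield_psf_model`.
#' @export
brightfield_psf_model <- function(NA_ = 0.75, lambda_center = 0.55,
                                  sigma0 = NULL, z_R = NULL) {
  if (NA_ <= 0 || NA_ >= 1) stop("NA must be in (0, 1)", call. = FALSE)
  sigma0 <- sigma0 %||% (0.61 * lambda_center / NA_)
  z_R <- z_R %||% (lambda_center / NA_^2)
  structure(list(NA_ = NA_, lambda_center = lambda_center,
                 sigma0 = sigma0, z_R = z_R),
            class = "brightfield_psf_model")
}

# defocus blur sigma at axial distance dz (um)
bf_sigma <- function(model, dz) model$sigma0 * sqrt(1 + (dz / model$z_R)^2)

# FFT Gaussian blur of a matrix with sigma in pixels (periodic boundaries;
# fields of interest have a uniform border so wrap-around is benign)
.gauss_blur <- function(img, sigma_px) {
  if (sigma_px < 1e-3) return(img)
  n <- nrow(img); m <- ncol(img)
  fy <- fft_freq(n, 1); fx <- fft_freq(m, 1)
  H <- exp(-2 * pi^2 * sigma_px^2 * outer(fy^2, fx^2, `+`))
  Re(stats::fft(stats::fft(img) * H, inverse = TRUE)) / (n * m)
}

#' Render an incoherent bright-field color z-stack of a phantom
#'
#' For every requested plane each particle contributes a disk of its color
#' and absorption, blurred by the model's defocus Gaussian at the
#' particle-to-plane distance, composited multiplicatively onto a white
#' background. Strictly incoherent: no interference fringes at any defocus.
#'
#' @param phantom a [generate_phantom()] result.
#' @param z_list plane heights in um (same axis as scatterer z).
#' @param dims integer (rows, cols) of each plane.
#' @param pitch lateral pitch in um.
#' @param psf_model a [brightfield_psf_model()].
#' @return a [field_stack()] of modality "brightfield_gt" whose planes are
#'   (rows, cols, 3) arrays in [0, 1].
#' @export
render_brightfield_stack <- function(phantom, z_list, dims, pitch,
                                     psf_model = brightfield_psf_model()) {
  stopifnot(inherits(phantom, "phantom"))
  planes <- lapply(sort(z_list), function(zp) {
    plane <- array(1, c(dims[1], dims[2], 3))
    for (s in phantom$scatterers) {
      cov <- disk_coverage(dims[1], dims[2], pitch, s$x, s$y, s$radius)
      if (all(cov == 0)) next
      sig_px <- bf_sigma(psf_model, s$z - zp) / pitch
      blur <- .gauss_blur(cov, sig_px)
      blur <- pmin(pmax(blur, 0), 1)
      for (ch in 1:3) {
        # transmittance inside the particle: (1 - absorption) * color
        a_ch <- 1 - (1 - s$absorption) * s$color[ch]
        plane[, , ch] <- plane[, , ch] * (1 - a_ch * blur)
      }
    }
    plane
  })
  field_stack(planes, sort(z_list), pitch, "brightfield_gt")
}

#' Build a paired hologram / bright-field training dataset
#'
#' The self-contained data path: for each phantom, simulate the in-line
#' hologram, backpropagate it to the bright-field plane heights (3x spectral
#' interpolation so both modalities share a pitch), render the incoherent
#' bright-field stack at the interpolated pitch, and cut registered patch
#' pairs. Phantom ids are split disjointly into train/val/test; every random
#' draw descends from `seed` through named substreams.
#'
#' @param n_phantoms number of phantoms.
#' @param config list of generation settings; see Details. Any subset may be
#'   given; the rest use defaults sized for desk-scale runs.
#' @param seed master seed.
#' @return a list with `train`, `val`, `test` (lists of pairs as in
#'   [make_registered_pairs()], each pair also carrying `phantom_id`), and a
#'   `manifest` data.frame recording every patch.
#' @details Config entries and defaults: `dims` (64, 64) sensor px;
#'   `n_beads` 3; `z_center` 500 um; `z_spread` 8 um; `z_step` 2 um;
#'   `z_half_range` 20 um; `radius` 0.5 um; `absorption` 0.9;
#'   `noise_sd` 0.005; `patch` 64; `stride` 64; `pad_factor` 3;
#'   `split` c(train = .7, val = .15, test = .15); `colors` NULL;
#'   `register` FALSE (synthetic pairs are aligned by construction).
#' @export
build_paired_dataset <- function(n_phantoms, config = list(), seed = 1) {
  cfg <- utils::modifyList(list(
    dims = c(64, 64), n_beads = 3, z_center = 500, z_spread = 8,
    z_step = 2, z_half_range = 20, radius = 0.5, absorption = 0.9,
    noise_sd = 0.005, patch = 64, stride = 64, pad_factor = 3,
    split = c(train = 0.7, val = 0.15, test = 0.15),
    colors = NULL, register = FALSE, geometry = optical_geometry()),
    config)
  geom <- cfg$geometry
  extent <- cfg$dims[2] * geom$pixel_pitch
  z_list <- seq(-cfg$z_half_range, cfg$z_half_range, by = cfg$z_step)
  n_each <- pmax(round(cfg$split * n_phantoms), 0)
  while (sum(n_each) > n_phantoms) n_each[which.max(n_each)] <-
    n_each[which.max(n_each)] - 1
  while (sum(n_each) < n_phantoms) n_each[1] <- n_each[1] + 1
  split_of <- with_seed(substream_seed(seed, "split"),
                        sample(rep(names(n_each), n_each)))
  out <- list(train = list(), val = list(), test = list())
  manifest <- list()
  for (pid in seq_len(n_phantoms)) {
    ph_seed <- substream_seed(seed, paste0("phantom", pid))
    ph <- generate_phantom(cfg$n_beads, extent,
                           cfg$z_center + c(-1, 1) * cfg$z_spread / 2,
                           radius_dist = c(cfg$radius, 0),
                           min_separation = 8, absorption = cfg$absorption,
                           colors = cfg$colors,
                           margin = max(4, 6 * geom$pixel_pitch),
                           seed = ph_seed)
    holo <- simulate_inline_hologram(ph, geom, cfg$dims,
                                     noise_sd = cfg$noise_sd,
                                     seed = substream_seed(seed,
                                                           paste0("noise", pid)))
    z_ref <- mean(vapply(ph$scatterers, `[[`, numeric(1), "z"))
    bp <- backpropagate_hologram(holo, z_ref + z_list,
                                 pad_factor = cfg$pad_factor)
    bp$z_list <- bp$z_list - z_ref          # re-center on the focal plane
    fine_dims <- dim(bp$planes[[1]])
    bf <- render_brightfield_stack(ph, z_ref + z_list, fine_dims, bp$pitch)
    bf$z_list <- bf$z_list - z_ref
    pairs <- make_registered_pairs(bp, bf, patch = cfg$patch,
                                   stride = cfg$stride,
                                   register = cfg$register)
    sp <- split_of[pid]
    for (pr in pairs) {
      pr$phantom_id <- pid
      out[[sp]][[length(out[[sp]]) + 1]] <- pr
      manifest[[length(manifest) + 1]] <- data.frame(
        phantom_id = pid, split = sp, z = pr$z, row = pr$row, col = pr$col)
    }
  }
  out$manifest <- do.call(rbind, manifest)
  out
}
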