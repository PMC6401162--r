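# End-to-end evaluation protocols used by the package's own validation: each
# runs the full pipeline at desk scale and reports the summary quantities a
# study of the method would quote.

#' Autofocus recovery benchmark
#'
#' Simulates seeded sparse-bead holograms with focal planes spread over
#' 450-550 um, runs [autofocus()] over a 400-600 um search range, and
#' reports the recovery-error distribution.
#'
#' @param n_holograms number of holograms (default 100).
#' @param seed master seed.
#' @param dims sensor grid (default 96 x 96).
#' @param n_beads beads per hologram (default 3).
#' @param noise_sd sensor noise level (default 0.01).
#' @return a list: `errors` (um, signed), `rate_within_2um`.
#' @export
benchmark_autofocus <- function(n_holograms = 100, seed = 1,
                                dims = c(96, 96), n_beads = 3,
                                noise_sd = 0.01) {
  ext <- dims[2] * 1.12
  errors <- vapply(seq_len(n_holograms), function(i) {
    z_true <- 450 + ((substream_seed(seed, paste0("zpick", i)) %% 1001) / 10)
    ph <- generate_phantom(n_beads, ext, z_true + c(-2, 2),
                           radius_dist = c(0.5, 0), min_separation = 8,
                           absorption = 0.9,
                           seed = substream_seed(seed, paste0("ph", i)))
    holo <- simulate_inline_hologram(ph, optical_geometry(), dims,
                                     noise_sd = noise_sd,
                                     seed = substream_seed(seed,
                                                           paste0("ns", i)))
    zc <- mean(vapply(ph$scatterers, `[[`, numeric(1), "z"))
    af <- autofocus(holo, 400, 600, coarse_step = 10, tol = 0.1)
    af$z_star - zc
  }, numeric(1))
  list(errors = errors, rate_within_2um = mean(abs(errors) <= 2))
}

#' Phase-recovery benchmark on a simulated disk hologram
#'
#' Measures twin-image suppression and in-focus CNR improvement of
#' object-support phase recovery against plain backpropagation.
#'
#' @param seed master seed.
#' @param radius disk radius in um (default 4).
#' @param iterations recovery iterations (default 100).
#' @return a list: `twin_reduction` (fraction removed), `cnr_backprop`,
#'   `cnr_recovered`.
#' @export
benchmark_phase_recovery <- function(seed = 1, radius = 4,
                                     iterations = 100) {
  n <- 128; ext <- n * 1.12
  ph <- structure(list(
    scatterers = list(scatterer(ext / 2, ext / 2, 500, radius = radius,
                                absorption = 0.9)),
    lateral_extent = ext, z_range = c(500, 500), min_separation = 10,
    seed = seed), class = "phantom")
  holo <- simulate_inline_hologram(ph, optical_geometry(), c(n, n),
                                   noise_sd = 0.005,
                                   seed = substream_seed(seed, "noise"))
  bp <- backpropagate_hologram(holo, 500, pad_factor = 1)
  amp0 <- Mod(bp$planes[[1]])
  sup <- estimate_support(amp0, k = 2, dilation = 6)
  rec <- iterative_phase_recovery(holo, 500, sup, iterations = iterations)
  D <- disk_coverage(n, n, 1.12, ext / 2, ext / 2, radius) > 0
  true_sup <- EBImage::dilate(matrix(as.numeric(D), n),
                              EBImage::makeBrush(13, "disc")) > 0.5
  e0 <- twin_image_energy(bp$planes[[1]], true_sup)
  e1 <- twin_image_energy(rec$values, true_sup)
  bg <- !(EBImage::dilate(matrix(as.numeric(D), n),
                          EBImage::makeBrush(41, "disc")) > 0.5)
  list(twin_reduction = 1 - e1 / e0,
       cnr_backprop = compute_cnr(amp0, D, bg)$cnr,
       cnr_recovered = compute_cnr(Mod(rec$values), D, bg)$cnr)
}

# stratified training subset: every patch showing object contrast plus an
# equal number of background-only patches (bright-field targets are almost
# entirely white, so unstratified sampling starves the regression signal)
.balance_pairs <- function(pairs, thresh = 0.97, seed = 1) {
  tmin <- vapply(pairs, function(p) min(p$target), numeric(1))
  dark <- which(tmin < thresh); light <- which(tmin >= thresh)
  with_seed(seed, {
    keep <- c(dark, sample(light, min(length(dark), length(light))))
    pairs[sample(keep)]
  })
}

#' Cross-modality benchmark: train a desk-scale model and measure 3-D PSFs
#'
#' The package's core end-to-end experiment. Builds paired synthetic data
#' (fine axial sampling through focus plus coarse far-defocus coverage),
#' trains the cross-modality generator, and evaluates held-out multi-bead
#' phantoms: per-bead axial FWHM of the backpropagated input, the network
#' output and the bright-field ground truth, plus out-of-focus fringe energy
#' of input vs output.
#'
#' @param seed master seed.
#' @param n_phantoms training phantoms (default 10).
#' @param iterations training iterations (default 3000).
#' @param adversarial_weight GAN loss weight (default 0.02).
#' @param n_eval_phantoms held-out phantoms (default 3, 7 beads each).
#' @param gen_cfg generator configuration (desk-scale default: depth 2,
#'   8 base channels, 1 residual block).
#' @param verbose print training progress.
#' @return a list with the trained `model`, per-bead FWHM vectors
#'   (`axial_input`, `axial_output`, `axial_gt`), their medians
#'   (`median_axial_input`, `median_axial_output`, `median_axial_gt`),
#'   `fringe_ratio` (output / input out-of-focus high-pass energy) and
#'   `n_beads`.
#' @export
benchmark_cross_modality <- function(seed = 11, n_phantoms = 10,
                                     iterations = 3000,
                                     adversarial_weight = 0.02,
                                     n_eval_phantoms = 3,
                                     gen_cfg = generator_config(
                                       depth = 2, base_channels = 8,
                                       residual_blocks = 1),
                                     verbose = FALSE) {
  base_cfg <- list(dims = c(64, 64), n_beads = 5, z_spread = 10,
                   patch = 32, stride = 32, pad_factor = 3,
                   noise_sd = 0.005)
  ds_fine <- build_paired_dataset(
    n_phantoms, c(base_cfg, list(z_step = 0.5, z_half_range = 5)),
    seed = seed)
  ds_far <- build_paired_dataset(
    n_phantoms, c(base_cfg, list(z_step = 2.5, z_half_range = 20)),
    seed = seed)
  tr <- .balance_pairs(c(ds_fine$train, ds_far$train),
                       seed = substream_seed(seed, "balance"))
  va_all <- c(ds_fine$val, ds_far$val)
  vmin <- vapply(va_all, function(p) min(p$target), numeric(1))
  va <- va_all[c(utils::head(which(vmin < 0.97), 16),
                 utils::head(which(vmin >= 0.97), 8))]
  model <- train_brightfield_gan(
    tr, va, gen_cfg, discriminator_config(base_channels = 8),
    training_config(max_iterations = iterations,
                    adversarial_weight = adversarial_weight,
                    seed = substream_seed(seed, "train")),
    verbose = verbose)
  ax_in <- ax_out <- ax_gt <- fr_in <- fr_out <- numeric(0)
  for (pid in seq_len(n_eval_phantoms)) {
    ext <- 96 * 1.12
    ph <- generate_phantom(7, ext, c(492, 508), radius_dist = c(0.5, 0),
                           min_separation = 26, absorption = 0.9,
                           margin = 12,
                           seed = substream_seed(seed, paste0("ev", pid)))
    holo <- simulate_inline_hologram(ph, optical_geometry(), c(96, 96),
                                     noise_sd = 0.005,
                                     seed = substream_seed(seed,
                                                           paste0("en", pid)))
    zl <- seq(480, 520, by = 0.5)
    bp <- backpropagate_hologram(holo, zl, pad_factor = 3)
    bf <- render_brightfield_stack(ph, zl, dim(bp$planes[[1]]), bp$pitch)
    net <- infer_stack(model, bp, tile = 64, overlap = 16)
    det <- detect_beads(bf, min_separation = 16)
    if (nrow(det) == 0) next
    s_in <- bead_psf_stats(bp, det)
    s_gt <- bead_psf_stats(bf, det)
    s_out <- tryCatch(bead_psf_stats(net, det), error = function(e) NULL)
    if (is.null(s_out)) next
    ax_in <- c(ax_in, s_in$beads$fwhm_axial)
    ax_gt <- c(ax_gt, s_gt$beads$fwhm_axial)
    ax_out <- c(ax_out, s_out$beads$fwhm_axial)
    for (k in c(1, length(zl))) {                  # |dz| = 20 um planes
      fr_in <- c(fr_in, fringe_energy(bp$planes[[k]], bp$pitch))
      fr_out <- c(fr_out, fringe_energy(net$planes[[k]], net$pitch))
    }
  }
  list(model = model,
       axial_input = ax_in, axial_output = ax_out, axial_gt = ax_gt,
       median_axial_input = stats::median(ax_in),
       median_axial_output = stats::median(ax_out),
       median_axial_gt = stats::median(ax_gt),
       fringe_ratio = mean(fr_out) / mean(fr_in),
       n_beads = length(ax_out))
}
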