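#' Estimate an object-support mask from a reconstructed amplitude
#'
#' Pixels whose amplitude departs from the background by more than `k`
#' standard deviations (dark absorbing objects or bright phase artifacts) are
#' flagged and morphologically dilated by a disk to form the support.
#'
#' @param amplitude finite real matrix (object-plane amplitude).
#' @param k threshold in standard deviations (default 1.5).
#' @param dilation dilation radius in pixels (default 6).
#' @return a list of class `support_mask`: logical `mask`, `k`, `dilation`.
#' @export
estimate_support <- function(amplitude, k = 1.5, dilation = 6) {
  if (!all(is.finite(amplitude)))
    stop("amplitude must be finite", call. = FALSE)
  mu <- mean(amplitude); s <- sd(amplitude)
  raw <- amplitude < mu - k * s | amplitude > mu + k * s
  if (!any(raw)) stop("empty support after thresholding", call. = FALSE)
  mask <- raw
  if (dilation > 0) {
    brush <- EBImage::makeBrush(2 * dilation + 1, shape = "disc")
    mask <- EBImage::dilate(matrix(as.numeric(raw), nrow(raw)), brush) > 0.5
  }
  structure(list(mask = mask, k = k, dilation = dilation),
            class = "support_mask")
}

#' Object-support iterative phase recovery
#'
#' The classical twin-image suppression baseline: alternate between the
#' measured sensor amplitude and an object-plane support constraint.
#' Per iteration the sensor field is backpropagated to the object plane;
#' outside the support the field is replaced by the background estimate
#' (mean amplitude outside the support, zero phase); the field is propagated
#' forward to the sensor where the amplitude is reset to sqrt(measured
#' intensity) while the recovered phase is kept. After the final iteration
#' the object-plane field is returned. `iterations = 0` reduces to plain
#' backpropagation.
#'
#' @param holo a preprocessed [hologram_frame()].
#' @param z object-plane height in um.
#' @param support a [estimate_support()] mask at the sensor grid size.
#' @param iterations number of constraint iterations (default 100).
#' @return a [complex_field()] at the object plane.
#' @export
iterative_phase_recovery <- function(holo, z, support, iterations = 100) {
  stopifnot(inherits(holo, "hologram_frame"),
            inherits(support, "support_mask"))
  if (iterations < 0) stop("iterations must be >= 0", call. = FALSE)
  if (!any(support$mask)) stop("empty support", call. = FALSE)
  g <- holo$geometry
  lam <- g$wavelength / g$medium_index
  amp_meas <- sqrt(pmax(holo$intensity, 0))
  u_sensor <- amp_meas + 0i
  sens <- function(u) complex_field(u, g$pixel_pitch, lam, 0)
  obj <- propagate(sens(u_sensor), z)$values
  if (iterations > 0) {
    for (it in seq_len(iterations)) {
      bg <- mean(Mod(obj)[!support$mask])
      obj[!support$mask] <- bg + 0i
      u_sensor <- propagate(complex_field(obj, g$pixel_pitch, lam, z),
                            -z)$values
      u_sensor <- amp_meas * exp(1i * Arg(u_sensor))
      obj <- propagate(sens(u_sensor), z)$values
    }
  }
  complex_field(obj, g$pixel_pitch, lam, z)
}

#' Twin-image energy outside a support
#'
#' Sum of |field - background|^2 over pixels outside the (optionally
#' externally supplied, e.g. ground-truth) support: the residual conjugate
#' artifact energy that phase recovery is meant to remove.
#'
#' @param field a [complex_field()] or complex matrix.
#' @param mask logical matrix: TRUE inside the object support.
#' @return nonnegative scalar.
#' @export
twin_image_energy <- function(field, mask) {
  v <- if (inherits(field, "complex_field")) field$values else field
  out <- v[!mask]
  bg <- mean(Mod(out))
  sum(Mod(out - bg)^2)
}
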