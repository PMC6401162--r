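#' Angular-spectrum free-space transfer function
#'
#' Builds the exact scalar transfer function
#' H(fx, fy) = exp(i 2 pi z sqrt(1/lambda^2 - fx^2 - fy^2)) on propagating
#' spatial frequencies (fx^2 + fy^2 <= 1/lambda^2) and 0 on evanescent ones.
#' The frequency grid follows the DFT convention for the given shape and
#' pitch, so the kernel multiplies an unshifted 2-D FFT directly.
#'
#' @param shape integer vector (rows, cols) of the field grid.
#' @param pitch sampling pitch in um (> 0).
#' @param wavelength wavelength in the medium, um (> 0).
#' @param z propagation distance in um (signed; negative backpropagates).
#' @return a complex matrix of dimension `shape`.
#' @export
angular_spectrum_kernel <- function(shape, pitch, wavelength, z) {
  if (!is.numeric(pitch) || pitch <= 0)
    stop("pitch must be > 0", call. = FALSE)
  if (!is.numeric(wavelength) || wavelength <= 0)
    stop("wavelength must be > 0", call. = FALSE)
  fy <- fft_freq(shape[1], pitch)
  fx <- fft_freq(shape[2], pitch)
  f2 <- outer(fy^2, fx^2, `+`)
  arg <- 1 / wavelength^2 - f2
  kz <- sqrt(pmax(arg, 0))
  H <- exp(2i * pi * z * kz)
  H[arg < 0] <- 0 + 0i   # evanescent components dropped
  H
}

#' Propagate a complex field through free space
#'
#' Frequency-domain multiplication with [angular_spectrum_kernel()]. Energy in
#' propagating components is conserved; evanescent components are discarded.
#'
#' @param field a [complex_field()].
#' @param dz propagation distance in um (signed).
#' @return a [complex_field()] with `z` incremented by `dz`.
#' @export
propagate <- function(field, dz) {
  stopifnot(inherits(field, "complex_field"))
  if (dz == 0) {
    field$z <- field$z + dz
    return(field)
  }
  H <- angular_spectrum_kernel(dim(field$values), field$pitch,
                               field$wavelength, dz)
  U <- stats::fft(field$values)
  out <- stats::fft(U * H, inverse = TRUE) / length(U)
  complex_field(out, field$pitch, field$wavelength, field$z + dz)
}

# Interpolate a complex sensor field by zero-padding its spectrum.
# Returns a grid of dims pad * dim(u) at pitch p / pad; amplitude preserved.
spectral_pad <- function(u, pad_factor) {
  if (pad_factor == 1) return(u)
  n1 <- nrow(u); n2 <- ncol(u)
  m1 <- n1 * pad_factor; m2 <- n2 * pad_factor
  U <- stats::fft(u)
  V <- matrix(0 + 0i, m1, m2)
  h1 <- floor(n1 / 2); h2 <- floor(n2 / 2)
  # low nonnegative frequencies stay at the top-left corner,
  # negative frequencies wrap to the far edge (DFT layout)
  i_lo <- seq_len(n1 - h1); i_hi <- if (h1 > 0) (n1 - h1 + 1):n1 else integer(0)
  j_lo <- seq_len(n2 - h2); j_hi <- if (h2 > 0) (n2 - h2 + 1):n2 else integer(0)
  V[i_lo, j_lo] <- U[i_lo, j_lo]
  if (length(i_hi)) V[m1 - h1 + seq_len(h1), j_lo] <- U[i_hi, j_lo]
  if (length(j_hi)) V[i_lo, m2 - h2 + seq_len(h2)] <- U[i_lo, j_hi]
  if (length(i_hi) && length(j_hi))
    V[m1 - h1 + seq_len(h1), m2 - h2 + seq_len(h2)] <- U[i_hi, j_hi]
  stats::fft(V, inverse = TRUE) * (pad_factor^2 / length(V))
}

#' Backpropagate a hologram to a list of object planes
#'
#' The measured intensity is converted to an initial sensor-plane field with
#' amplitude sqrt(intensity) and zero phase (the standard lensless
#' convention), optionally interpolated by zero-padding in the angular-spectrum
#' (Fourier) domain — `pad_factor = 3` refines the effective pixel pitch by
#' 3x — and propagated back to each requested object height (the exact
#' inverse of the sensor-bound forward propagation).
#'
#' @param holo a preprocessed [hologram_frame()] (unit mean intensity).
#' @param z_list object-plane distances from the sensor in um (nonempty).
#' @param pad_factor integer >= 1 spectral interpolation factor (default 3).
#' @return a [field_stack()] of modality "backpropagation" whose `z_list`
#'   matches the input order sorted increasing; output pitch is
#'   `pixel_pitch / pad_factor`.
#' @export
backpropagate_hologram <- function(holo, z_list, pad_factor = 3) {
  stopifnot(inherits(holo, "hologram_frame"))
  if (length(z_list) < 1) stop("z_list must be nonempty", call. = FALSE)
  if (pad_factor < 1 || pad_factor != round(pad_factor))
    stop("pad_factor must be a positive integer", call. = FALSE)
  g <- holo$geometry
  lam <- g$wavelength / g$medium_index
  u0 <- sqrt(pmax(holo$intensity, 0)) + 0i
  u0 <- spectral_pad(u0, pad_factor)
  pitch <- g$pixel_pitch / pad_factor
  U <- stats::fft(u0)
  z_sorted <- sort(z_list)
  planes <- lapply(z_sorted, function(z) {
    # the forward model propagates object -> sensor over -z, so the
    # reconstruction applies the exact inverse (+z); for the real-valued
    # initial amplitude the twin ambiguity makes |.| independent of the sign
    H <- angular_spectrum_kernel(dim(u0), pitch, lam, z)
    stats::fft(U * H, inverse = TRUE) / length(U)
  })
  field_stack(planes, z_sorted, pitch, "backpropagation", wavelength = lam)
}
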