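#' Acquisition geometry of the lensless in-line holographic microscope
#'
#' Bundles the physical constants of the recording geometry. Defaults follow
#' the reference setup: near-infrared illumination at 850 nm, a 1.12 um
#' sensor pixel pitch, and the sample mounted roughly 500 um above the sensor
#' in air.
#'
#' @param wavelength illumination wavelength in um (> 0).
#' @param pixel_pitch sensor pixel pitch in um (> 0).
#' @param z2 sample-to-sensor distance in um (> 0).
#' @param medium_index refractive index of the propagation medium (>= 1).
#' @return an object of class `optical_geometry`.
#' @export
optical_geometry <- function(wavelength = 0.85, pixel_pitch = 1.12,
                             z2 = 500, medium_index = 1) {
  if (!is.numeric(wavelength) || wavelength <= 0)
    stop("wavelength must be > 0", call. = FALSE)
  if (!is.numeric(pixel_pitch) || pixel_pitch <= 0)
    stop("pixel_pitch must be > 0", call. = FALSE)
  if (!is.numeric(z2) || z2 <= 0)
    stop("z2 must be > 0", call. = FALSE)
  if (!is.numeric(medium_index) || medium_index < 1)
    stop("medium_index must be >= 1", call. = FALSE)
  structure(list(wavelength = wavelength, pixel_pitch = pixel_pitch,
                 z2 = z2, medium_index = medium_index),
            class = "optical_geometry")
}

#' @export
print.optical_geometry <- function(x, ...) {
  cat(sprintf(
    "Optical geometry: lambda = %g um, pitch = %g um, z2 = %g um, n = %g\n",
    x$wavelength, x$pixel_pitch, x$z2, x$medium_index))
  invisible(x)
}

#' A complex optical field sampled on a regular grid
#'
#' The currency of all propagation: a 2-D complex amplitude with its physical
#' pixel pitch, wavelength and axial position. `z` is relative to the
#' registered "zero" (focal) plane and increases away from the sensor.
#'
#' @param values complex (or real, promoted) matrix, at least 2 x 2.
#' @param pitch sampling pitch in um.
#' @param wavelength wavelength in um.
#' @param z axial position in um.
#' @return an object of class `complex_field`.
#' @export
complex_field <- function(values, pitch, wavelength, z = 0) {
  if (!is.matrix(values) || nrow(values) < 2 || ncol(values) < 2)
    stop("values must be a matrix of at least 2 x 2", call. = FALSE)
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    stop("field values must be finite", call. = FALSE)
  if (pitch <= 0 || wavelength <= 0)
    stop("pitch and wavelength must be > 0", call. = FALSE)
  storage.mode(values) <- "complex"
  structure(list(values = values, pitch = pitch,
                 wavelength = wavelength, z = z),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("Complex field: %d x %d, pitch %g um, lambda %g um, z = %g um\n",
              nrow(x$values), ncol(x$values), x$pitch, x$wavelength, x$z))
  invisible(x)
}

#' A recorded in-line hologram frame
#'
#' @param intensity nonnegative real matrix with positive mean.
#' @param geometry an [optical_geometry()].
#' @param preprocessed logical flag: has the frame been shade corrected and
#'   normalized to unit mean?
#' @return an object of class `hologram_frame`.
#' @export
hologram_frame <- function(intensity, geometry = optical_geometry(),
                           preprocessed = FALSE) {
  if (!is.matrix(intensity) || !all(is.finite(intensity)))
    stop("intensity must be a finite matrix", call. = FALSE)
  if (any(intensity < 0)) stop("intensity must be nonnegative", call. = FALSE)
  if (mean(intensity) <= 0) stop("mean intensity must be > 0", call. = FALSE)
  stopifnot(inherits(geometry, "optical_geometry"))
  structure(list(intensity = intensity, geometry = geometry,
                 preprocessed = isTRUE(preprocessed)),
            class = "hologram_frame")
}

#' @export
print.hologram_frame <- function(x, ...) {
  cat(sprintf("Hologram frame: %d x %d, mean %.4g%s\n",
              nrow(x$intensity), ncol(x$intensity), mean(x$intensity),
              if (x$preprocessed) ", preprocessed" else ""))
  invisible(x)
}

#' A z-ordered stack of image planes at uniform axial step
#'
#' Planes may be complex matrices (backpropagation), RGB arrays
#' (bright-field ground truth or network output), or real matrices.
#'
#' @param planes list of planes, one per z.
#' @param z_list strictly increasing axial positions in um with uniform step.
#' @param pitch lateral pitch in um.
#' @param modality one of "backpropagation", "network_output",
#'   "brightfield_gt".
#' @param wavelength optional wavelength in um (coherent stacks).
#' @return an object of class `field_stack`.
#' @export
field_stack <- function(planes, z_list, pitch,
                        modality = c("backpropagation", "network_output",
                                     "brightfield_gt"),
                        wavelength = NULL) {
  modality <- match.arg(modality)
  if (length(planes) != length(z_list))
    stop("planes and z_list must have equal length", call. = FALSE)
  if (length(z_list) == 0) stop("stack must be nonempty", call. = FALSE)
  if (length(z_list) > 1) {
    dz <- diff(z_list)
    if (any(dz <= 0)) stop("z_list must be strictly increasing", call. = FALSE)
    if (max(dz) - min(dz) > 1e-9)
      stop("z_list must have a uniform step", call. = FALSE)
  }
  structure(list(planes = planes, z_list = as.numeric(z_list), pitch = pitch,
                 modality = modality, wavelength = wavelength),
            class = "field_stack")
}

#' @export
print.field_stack <- function(x, ...) {
  dz <- if (length(x$z_list) > 1) diff(x$z_list)[1] else NA_real_
  cat(sprintf("Field stack (%s): %d planes, z in [%g, %g] um, dz = %g um\n",
              x$modality, length(x$planes), min(x$z_list), max(x$z_list), dz))
  invisible(x)
}

#' @export
length.field_stack <- function(x) length(x$planes)

# amplitude image of a plane regardless of storage type
plane_amplitude <- function(plane) {
  if (is.complex(plane)) Mod(plane)
  else if (length(dim(plane)) == 3) {
    # luminance of an RGB plane
    0.2126 * plane[, , 1] + 0.7152 * plane[, , 2] + 0.0722 * plane[, , 3]
  } else plane
}
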