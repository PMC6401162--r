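# Orthogonal wavelet filters used for shade estimation. Hard-coded sym4
# (least-asymmetric Daubechies, 8 taps) decomposition low-pass; the full
# filter bank is derived from it by the standard quadrature-mirror relations.
.sym4_lo <- c(-0.07576571478927333, -0.02963552764599851,
              0.49761866763201545, 0.80373875180591614,
              0.29785779560527736, -0.09921954357684722,
              -0.01260396726203783, 0.03222310060404270)

.wavelet_filters <- function() {
  lo_d <- .sym4_lo
  n <- length(lo_d)
  hi_d <- rev(lo_d) * (-1)^(seq_len(n) - 1)
  list(lo_d = lo_d, hi_d = hi_d, lo_r = rev(lo_d), hi_r = rev(hi_d))
}

# Periodized analysis: a[j] = sum_k h[k] x[(2j + k) mod n], stride-2
# correlation. The synthesis below is its exact transpose, so the periodized
# orthogonal filter bank reconstructs perfectly.
.dwt_step <- function(x, h) {
  n <- length(x)
  half <- n / 2
  acc <- numeric(half)
  for (k in seq_along(h)) {
    idx <- ((2 * (seq_len(half) - 1) + k - 1) %% n) + 1
    acc <- acc + h[k] * x[idx]
  }
  acc
}

# transpose of .dwt_step applied to both bands
.idwt_step <- function(a, d, lo_d, hi_d) {
  n <- 2 * length(a)
  out <- numeric(n)
  for (k in seq_along(lo_d)) {
    idx <- ((2 * (seq_along(a) - 1) + k - 1) %% n) + 1
    contrib <- lo_d[k] * a + hi_d[k] * d
    # scatter-add; idx values are unique for fixed k
    out[idx] <- out[idx] + contrib
  }
  out
}

# Multi-level 2-D approximation: mirror-pad (symmetric boundary handling),
# decompose `levels` times keeping only the approximation band, reconstruct
# with all detail bands zeroed, crop.
.wavelet_approx <- function(img, levels) {
  flt <- .wavelet_filters()
  n0 <- nrow(img); m0 <- ncol(img)
  a <- rbind(img, img[n0:1, , drop = FALSE])
  a <- cbind(a, a[, m0:1, drop = FALSE])
  dims_hist <- list()
  for (l in seq_len(levels)) {
    if (min(dim(a)) < 2 * length(flt$lo_d)) break   # grid exhausted
    if (nrow(a) %% 2 == 1) a <- rbind(a, a[nrow(a), ])
    if (ncol(a) %% 2 == 1) a <- cbind(a, a[, ncol(a)])
    dims_hist[[l]] <- dim(a)
    a <- apply(a, 2, .dwt_step, h = flt$lo_d)        # columns
    a <- t(apply(t(a), 2, .dwt_step, h = flt$lo_d))  # rows
  }
  for (l in rev(seq_along(dims_hist))) {
    # rows back first (inverse order of analysis), then columns
    zr <- matrix(0, nrow(a), ncol(a))
    a <- t(vapply(seq_len(nrow(a)),
                  function(i) .idwt_step(a[i, ], zr[i, ], flt$lo_d, flt$hi_d),
                  numeric(2 * ncol(a))))
    zc <- matrix(0, nrow(a), ncol(a))
    a <- vapply(seq_len(ncol(a)),
                function(j) .idwt_step(a[, j], zc[, j], flt$lo_d, flt$hi_d),
                numeric(2 * nrow(a)))
    a <- a[seq_len(dims_hist[[l]][1]), seq_len(dims_hist[[l]][2]),
           drop = FALSE]
  }
  a[seq_len(n0), seq_len(m0), drop = FALSE]
}

#' Extract the four Bayer channels of a mosaicked sensor frame
#'
#' Near-infrared illumination makes all four channels of a color sensor
#' respond, so each half-resolution channel carries an independently sampled
#' copy of the hologram; they are shade corrected separately and re-merged to
#' recover the full sensor sampling.
#'
#' @param raw mosaicked matrix with even dimensions.
#' @param bayer_order one of "RGGB", "BGGR", "GRBG", "GBRG".
#' @return a named list of four (H/2, W/2) matrices `ch1..ch4` in raster
#'   order (top-left, top-right, bottom-left, bottom-right of each 2x2 cell),
#'   plus the `bayer_order`.
#' @export
extract_bayer_channels <- function(raw, bayer_order = "RGGB") {
  if (!is.matrix(raw)) stop("raw must be a matrix", call. = FALSE)
  if (nrow(raw) %% 2 != 0 || ncol(raw) %% 2 != 0)
    stop("raw frame must have even dimensions", call. = FALSE)
  bayer_order <- match.arg(bayer_order, c("RGGB", "BGGR", "GRBG", "GBRG"))
  ri <- seq(1, nrow(raw), by = 2); ci <- seq(1, ncol(raw), by = 2)
  list(ch1 = raw[ri, ci], ch2 = raw[ri, ci + 1],
       ch3 = raw[ri + 1, ci], ch4 = raw[ri + 1, ci + 1],
       bayer_order = bayer_order)
}

#' Shade-correct one channel by wavelet background division
#'
#' Estimates the slowly varying illumination shade as the level-`levels`
#' wavelet approximation of the channel (all detail coefficients zeroed) and
#' divides it out; illumination shade is multiplicative, so division — not
#' subtraction — flattens the background while preserving fringe contrast.
#' The output is renormalized to unit mean.
#'
#' @param channel finite matrix with positive mean.
#' @param levels decomposition depth (default 6: shade scale >= ~64 px).
#' @return the corrected matrix, mean 1.
#' @export
shade_correct <- function(channel, levels = 6) {
  if (!all(is.finite(channel))) stop("channel must be finite", call. = FALSE)
  if (mean(channel) <= 0)
    stop("channel mean must be > 0", call. = FALSE)
  shade <- .wavelet_approx(channel, levels)
  if (any(shade <= 0))
    stop("degenerate shade estimate (non-positive values)", call. = FALSE)
  out <- channel / shade
  out / mean(out)
}

#' Re-interleave four shade-corrected Bayer channels into one hologram
#'
#' @param channels list with `ch1..ch4` as returned by
#'   [extract_bayer_channels()] (after per-channel correction).
#' @param geometry an [optical_geometry()] attached to the result.
#' @return a [hologram_frame()] at full sensor resolution, unit mean,
#'   flagged preprocessed.
#' @export
merge_channels_monochrome <- function(channels,
                                      geometry = optical_geometry()) {
  chs <- channels[c("ch1", "ch2", "ch3", "ch4")]
  d <- dim(chs[[1]])
  if (!all(vapply(chs, function(x) identical(dim(x), d), logical(1))))
    stop("channel dimensions must match", call. = FALSE)
  out <- matrix(0, 2 * d[1], 2 * d[2])
  ri <- seq(1, 2 * d[1], by = 2); ci <- seq(1, 2 * d[2], by = 2)
  out[ri, ci] <- chs$ch1; out[ri, ci + 1] <- chs$ch2
  out[ri + 1, ci] <- chs$ch3; out[ri + 1, ci + 1] <- chs$ch4
  out <- pmax(out, 0)
  out <- out / mean(out)
  hologram_frame(out, geometry, preprocessed = TRUE)
}

#' Full raw-frame conditioning pipeline
#'
#' Bayer extraction, per-channel mean balancing and wavelet shade correction,
#' and re-interleaving. Purely monochrome data (simulated holograms) can skip
#' this and use [shade_correct()] directly.
#'
#' @inheritParams extract_bayer_channels
#' @inheritParams shade_correct
#' @param geometry an [optical_geometry()].
#' @return a preprocessed [hologram_frame()].
#' @export
preprocess_raw_frame <- function(raw, bayer_order = "RGGB", levels = 6,
                                 geometry = optical_geometry()) {
  chs <- extract_bayer_channels(raw, bayer_order)
  for (k in c("ch1", "ch2", "ch3", "ch4")) {
    ch <- chs[[k]]
    ch <- ch / mean(ch)              # per-channel balance
    # channels are half resolution: one fewer level keeps the same
    # physical shade scale as `levels` at full resolution
    chs[[k]] <- shade_correct(ch, levels = max(1, levels - 1))
  }
  merge_channels_monochrome(chs, geometry)
}
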