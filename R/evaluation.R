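#' Image-quality metric report: RMSE, SSIM, UIQI
#'
#' RMSE over all channels; SSIM with the standard 11x11 Gaussian window
#' (sigma 1.5) and default stabilizers C1 = (0.01 L)^2, C2 = (0.03 L)^2;
#' UIQI as the global single-window universal image quality index
#' Q = 4 sigma_xy mx my / ((sigma_x^2 + sigma_y^2)(mx^2 + my^2)).
#' Multichannel images are scored per channel and averaged.
#'
#' @param test,reference numeric arrays of equal dimensions (matrices or
#'   RGB arrays), values on a common scale.
#' @param data_range dynamic range L for SSIM (default 1).
#' @return a list of class `metric_report`: `rmse`, `ssim`, `uiqi`.
#' @export
compute_metrics <- function(test, reference, data_range = 1) {
  if (!identical(dim(test), dim(reference)))
    stop("image dimensions must match", call. = FALSE)
  if (sd(reference) == 0)
    stop("constant reference: ssim/uiqi undefined", call. = FALSE)
  rmse <- sqrt(mean((test - reference)^2))
  as_ch <- function(x) if (length(dim(x)) == 3)
    lapply(seq_len(dim(x)[3]), function(c) x[, , c]) else list(x)
  tc <- as_ch(test); rc <- as_ch(reference)
  ssim <- mean(mapply(.ssim_single, tc, rc,
                      MoreArgs = list(L = data_range)))
  uiqi <- mean(mapply(.uiqi_single, tc, rc))
  structure(list(rmse = rmse, ssim = ssim, uiqi = uiqi),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("RMSE %.5f | SSIM %.5f | UIQI %.5f\n", x$rmse, x$ssim, x$uiqi))
  invisible(x)
}

# separable 'valid' correlation with a symmetric 1-D window
.sep_conv_valid <- function(img, w) {
  cols <- apply(img, 2, function(v) stats::convolve(v, w, type = "filter"))
  t(apply(t(cols), 2, function(v) stats::convolve(v, w, type = "filter")))
}

.ssim_single <- function(x, y, L = 1, size = 11, sigma = 1.5) {
  r <- seq_len(size) - (size + 1) / 2
  w <- exp(-r^2 / (2 * sigma^2))
  w <- w / sum(w)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  f <- function(img) .sep_conv_valid(img, w)
  mx <- f(x); my <- f(y)
  sxx <- f(x * x) - mx^2; syy <- f(y * y) - my^2; sxy <- f(x * y) - mx * my
  num <- (2 * mx * my + C1) * (2 * sxy + C2)
  den <- (mx^2 + my^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

.uiqi_single <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  den <- (vx + vy) * (mx^2 + my^2)
  if (den == 0) stop("undefined UIQI (degenerate moments)", call. = FALSE)
  4 * cxy * mx * my / den
}

#' Contrast-to-noise ratio of a region pair
#'
#' CNR = |mean(foreground) - mean(background)| / sd(background).
#'
#' @param image real matrix (use amplitude or luminance for complex/RGB).
#' @param fg_mask,bg_mask disjoint logical masks, each with >= 25 pixels.
#' @return a list of class `cnr_measure`: `cnr`, `mu_fg`, `mu_bg`, `sd_bg`.
#' @export
compute_cnr <- function(image, fg_mask, bg_mask) {
  if (any(fg_mask & bg_mask)) stop("masks must be disjoint", call. = FALSE)
  if (sum(fg_mask) < 25 || sum(bg_mask) < 25)
    stop("each mask needs at least 25 pixels", call. = FALSE)
  mu_fg <- mean(image[fg_mask]); mu_bg <- mean(image[bg_mask])
  s_bg <- sd(image[bg_mask])
  if (s_bg == 0) stop("constant background: CNR undefined", call. = FALSE)
  structure(list(cnr = abs(mu_fg - mu_bg) / s_bg,
                 mu_fg = mu_fg, mu_bg = mu_bg, sd_bg = s_bg),
            class = "cnr_measure")
}

#' @export
print.cnr_measure <- function(x, ...) {
  cat(sprintf("CNR %.3f (fg %.4f, bg %.4f +/- %.4f)\n",
              x$cnr, x$mu_fg, x$mu_bg, x$sd_bg))
  invisible(x)
}

# stack -> 3-D "signal" array where beads are positive peaks
.stack_signal <- function(stack) {
  arr <- vapply(stack$planes, function(p) {
    a <- plane_amplitude(p)
    m <- stats::median(a)
    abs(a - m)                 # dark dips and bright peaks both positive
  }, matrix(0, nrow(plane_amplitude(stack$planes[[1]])),
            ncol(plane_amplitude(stack$planes[[1]]))))
  arr
}

#' Detect isolated beads in a z-stack
#'
#' Finds 3-D local maxima of the contrast signal above an adaptive threshold
#' (mean + 4 sd by default), refines each centroid by center of mass in a
#' 5x5x5 neighborhood, and enforces isolation: any pair of detections closer
#' than `min_separation` (3-D, um) removes both.
#'
#' @param stack a [field_stack()] (amplitude, intensity or RGB planes).
#' @param min_separation isolation distance in um (default 5).
#' @param k threshold in standard deviations above the mean (default 4).
#' @return a data.frame with columns `x`, `y`, `z` (um) and `signal`;
#'   possibly empty.
#' @export
detect_beads <- function(stack, min_separation = 5, k = 4) {
  stopifnot(inherits(stack, "field_stack"))
  sig <- .stack_signal(stack)
  d <- dim(sig)
  thr <- mean(sig) + k * sd(sig)
  cand <- which(sig > thr, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      signal = numeric(0)))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]; s <- cand[i, 3]
    nb <- sig[max(1, r - 1):min(d[1], r + 1),
              max(1, c - 1):min(d[2], c + 1),
              max(1, s - 1):min(d[3], s + 1)]
    keep[i] <- sig[r, c, s] >= max(nb)
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      signal = numeric(0)))
  dz <- if (length(stack$z_list) > 1) diff(stack$z_list)[1] else 1
  # merge multiple maxima of the same bead (e.g. axial contrast oscillations
  # of a coherent reconstruction): strongest-first clustering within
  # min_separation / 2 in physical units, keeping the strongest per cluster
  vals <- sig[cand]
  ord <- order(-vals)
  cand <- cand[ord, , drop = FALSE]; vals <- vals[ord]
  py <- cand[, 1] * stack$pitch; px <- cand[, 2] * stack$pitch
  pz <- cand[, 3] * dz
  taken <- rep(FALSE, nrow(cand)); sel <- integer(0)
  merge_r <- min_separation / 2
  for (i in seq_len(nrow(cand))) {
    if (taken[i]) next
    sel <- c(sel, i)
    if (i < nrow(cand)) {
      rest <- (i + 1):nrow(cand)
      # lateral-only distance: axial sidelobes of one bead stay one bead
      dd <- sqrt((px[rest] - px[i])^2 + (py[rest] - py[i])^2)
      taken[rest[dd <= merge_r]] <- TRUE
    }
  }
  cand <- cand[sel, , drop = FALSE]
  cent <- t(apply(cand, 1, function(rc) {
    ri <- max(1, rc[1] - 2):min(d[1], rc[1] + 2)
    ci <- max(1, rc[2] - 2):min(d[2], rc[2] + 2)
    si <- max(1, rc[3] - 2):min(d[3], rc[3] + 2)
    w <- sig[ri, ci, si]
    sw <- sum(w)
    c(sum(slice.index(w, 1) * w) / sw + ri[1] - 1,
      sum(slice.index(w, 2) * w) / sw + ci[1] - 1,
      sum(slice.index(w, 3) * w) / sw + si[1] - 1)
  }))
  res <- data.frame(
    x = (cent[, 2] - 0.5) * stack$pitch,
    y = (cent[, 1] - 0.5) * stack$pitch,
    z = stack$z_list[1] + (cent[, 3] - 1) * dz,
    signal = sig[cand])
  # isolation: drop both members of any close pair
  if (nrow(res) > 1) {
    drop <- rep(FALSE, nrow(res))
    for (i in seq_len(nrow(res) - 1))
      for (j in (i + 1):nrow(res)) {
        dist <- sqrt((res$x[i] - res$x[j])^2 + (res$y[i] - res$y[j])^2 +
                     (res$z[i] - res$z[j])^2)
        if (dist < min_separation) drop[i] <- drop[j] <- TRUE
      }
    res <- res[!drop, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Full width at half maximum of a sampled 1-D profile
#'
#' The half-maximum level is (extremum + baseline) / 2, with the baseline
#' taken as the median of the outer 20% of samples; crossings on each side
#' of the peak are located by linear interpolation.
#'
#' @param profile numeric vector with a unique interior global extremum
#'   (peaks; invert dips first).
#' @param spacing sample spacing in um.
#' @return FWHM in um.
#' @export
measure_fwhm <- function(profile, spacing) {
  n <- length(profile)
  if (n < 5) stop("profile too short", call. = FALSE)
  i_pk <- which.max(profile)
  if (i_pk == 1 || i_pk == n)
    stop("extremum at the boundary: not measurable", call. = FALSE)
  n_out <- max(1, floor(0.1 * n))
  baseline <- stats::median(c(profile[seq_len(n_out)],
                              profile[n - seq_len(n_out) + 1]))
  half <- (profile[i_pk] + baseline) / 2
  if (profile[i_pk] <= baseline)
    stop("no peak above baseline: not measurable", call. = FALSE)
  left <- NA_real_
  for (i in seq(i_pk - 1, 1)) {
    if (profile[i] <= half) {
      left <- i + (half - profile[i]) / (profile[i + 1] - profile[i])
      break
    }
  }
  right <- NA_real_
  for (i in seq(i_pk + 1, n)) {
    if (profile[i] <= half) {
      right <- i - (half - profile[i]) / (profile[i - 1] - profile[i])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop("half-maximum crossing not found: not measurable", call. = FALSE)
  (right - left) * spacing
}

#' Per-bead 3-D PSF statistics
#'
#' For each detected bead: the lateral FWHM of the contrast profile along x
#' through the centroid at the nearest-to-focus plane (dark dips inverted so
#' bright-field dips and coherent amplitude structures share one code path),
#' and the axial FWHM of the per-plane contrast extremum in a small lateral
#' window around the centroid. Beads whose profiles are not measurable are
#' dropped and counted.
#'
#' @param stack a [field_stack()].
#' @param centroids data.frame from [detect_beads()].
#' @param window lateral half-window in px for the axial profile (default 3).
#' @return a list: `beads` (data.frame bead_id, x, y, z, fwhm_lateral,
#'   fwhm_axial), `median_lateral`, `median_axial`, `n_dropped`.
#' @export
bead_psf_stats <- function(stack, centroids, window = 3) {
  stopifnot(inherits(stack, "field_stack"))
  if (nrow(centroids) == 0) stop("no centroids given", call. = FALSE)
  dz <- if (length(stack$z_list) > 1) diff(stack$z_list)[1] else 1
  amp <- lapply(stack$planes, plane_amplitude)
  d <- dim(amp[[1]])
  rows <- list(); dropped <- 0
  for (b in seq_len(nrow(centroids))) {
    r <- round(centroids$y[b] / stack$pitch + 0.5)
    c <- round(centroids$x[b] / stack$pitch + 0.5)
    kz <- which.min(abs(stack$z_list - centroids$z[b]))
    r <- min(max(r, 1), d[1]); c <- min(max(c, 1), d[2])
    res <- tryCatch({
      a <- amp[[kz]]
      prof_x <- a[r, ]
      bg <- stats::median(a)
      prof_x <- if (a[r, c] < bg) bg - prof_x else prof_x - bg
      fl <- measure_fwhm(prof_x, stack$pitch)
      ri <- max(1, r - window):min(d[1], r + window)
      ci <- max(1, c - window):min(d[2], c + window)
      prof_z <- vapply(amp, function(p) {
        w <- p[ri, ci]
        max(abs(w - stats::median(p)))
      }, numeric(1))
      fa <- measure_fwhm(prof_z, dz)
      c(fl, fa)
    }, error = function(e) NULL)
    if (is.null(res)) { dropped <- dropped + 1; next }
    rows[[length(rows) + 1]] <- data.frame(
      bead_id = b, x = centroids$x[b], y = centroids$y[b],
      z = centroids$z[b], fwhm_lateral = res[1], fwhm_axial = res[2])
  }
  if (length(rows) == 0)
    stop("no measurable beads", call. = FALSE)
  beads <- do.call(rbind, rows)
  list(beads = beads,
       median_lateral = stats::median(beads$fwhm_lateral),
       median_axial = stats::median(beads$fwhm_axial),
       n_dropped = dropped)
}

#' High-pass fringe energy of a plane
#'
#' Energy above a spatial-frequency cutoff, as a fraction of total AC
#' energy: the footprint of coherent out-of-focus fringes that incoherent
#' imaging does not show.
#'
#' @param plane real matrix or RGB array (luminance used).
#' @param pitch lateral pitch in um.
#' @param cutoff frequency cutoff in cycles/um (default 0.15).
#' @return nonnegative scalar (absolute high-pass energy per pixel).
#' @export
fringe_energy <- function(plane, pitch, cutoff = 0.15) {
  a <- plane_amplitude(if (is.complex(plane)) Mod(plane) else plane)
  a <- a - mean(a)
  Fa <- stats::fft(a)
  fy <- fft_freq(nrow(a), pitch); fx <- fft_freq(ncol(a), pitch)
  f2 <- outer(fy^2, fx^2, `+`)
  sum(Mod(Fa[f2 > cutoff^2])^2) / length(Fa)^2
}

#' Count sign changes of the radial derivative of a ring-averaged profile
#'
#' Diagnostic for coherent fringes: a defocused coherent particle image
#' oscillates radially (many sign changes), an incoherent blur is monotone
#' (at most one).
#'
#' @param plane real matrix or complex matrix (amplitude used).
#' @param center (row, col) center in px; default the darkest pixel.
#' @param max_radius radial extent in px (default 20).
#' @return integer count of derivative sign changes.
#' @export
radial_sign_changes <- function(plane, center = NULL, max_radius = 20) {
  a <- plane_amplitude(if (is.complex(plane)) Mod(plane) else plane)
  if (is.null(center)) {
    i <- which.min(a)
    center <- c((i - 1) %% nrow(a) + 1, (i - 1) %/% nrow(a) + 1)
  }
  rr <- slice.index(a, 1) - center[1]
  cc <- slice.index(a, 2) - center[2]
  rad <- sqrt(rr^2 + cc^2)
  prof <- vapply(seq_len(max_radius), function(k)
    mean(a[rad >= k - 1 & rad < k]), numeric(1))
  prof <- prof[is.finite(prof)]
  dp <- diff(prof)
  dp <- dp[abs(dp) > 1e-4 * max(abs(dp))]   # ignore numerically flat steps
  if (length(dp) < 2) return(0L)
  sum(diff(sign(dp)) != 0)
}
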