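#' A 2-D rigid transform (shift plus rotation)
#'
#' @param dx,dy shift in pixels (x = columns, y = rows).
#' @param theta rotation in degrees about the image center; pairings with
#'   |theta| >= 45 are rejected as implausible stage error.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(dx = 0, dy = 0, theta = 0) {
  if (abs(theta) >= 45) stop("|theta| must be < 45 degrees", call. = FALSE)
  structure(list(dx = dx, dy = dy, theta = theta), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("Rigid transform: dx = %.3f px, dy = %.3f px, theta = %.3f deg\n",
              x$dx, x$dy, x$theta))
  invisible(x)
}

# Bilinear sampling of img at (row, col) coordinate matrices; out-of-bounds
# pixels are filled with the image mean.
.bilinear_sample <- function(img, rr, cc, fill = mean(img)) {
  n <- nrow(img); m <- ncol(img)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  ok <- r0 >= 1 & r0 <= n - 1 & c0 >= 1 & c0 <= m - 1
  out <- matrix(fill, nrow(rr), ncol(rr))
  i00 <- cbind(r0[ok], c0[ok]);     i01 <- cbind(r0[ok], c0[ok] + 1)
  i10 <- cbind(r0[ok] + 1, c0[ok]); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
  out[ok] <- img[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
             img[i01] * (1 - fr[ok]) * fc[ok] +
             img[i10] * fr[ok] * (1 - fc[ok]) +
             img[i11] * fr[ok] * fc[ok]
  out
}

#' Apply a rigid transform to an image
#'
#' Rotates by `theta` about the image center and shifts by `(dx, dy)` pixels,
#' with bilinear interpolation; out-of-bounds samples are filled with the
#' image mean. `warp_rigid(img, estimate_rigid(img, ref))` aligns `img` onto
#' `ref`.
#'
#' @param img real matrix.
#' @param tf a [rigid_transform()].
#' @return the warped matrix, same dimensions.
#' @export
warp_rigid <- function(img, tf) {
  n <- nrow(img); m <- ncol(img)
  cy <- (n + 1) / 2; cx <- (m + 1) / 2
  th <- tf$theta * pi / 180
  # output pixel (r, c) samples input at the inverse transform
  rr0 <- matrix(seq_len(n), n, m) - cy
  cc0 <- matrix(seq_len(m), n, m, byrow = TRUE) - cx
  rr <- rr0 - tf$dy; cc <- cc0 - tf$dx
  rs <-  cos(th) * rr + sin(th) * cc
  cs <- -sin(th) * rr + cos(th) * cc
  .bilinear_sample(img, rs + cy, cs + cx)
}

# Phase correlation between equally sized images; returns list(dx, dy, peak)
# with subpixel refinement by 3-point parabolic interpolation.
.phase_correlate <- function(moving, fixed) {
  Fm <- stats::fft(moving - mean(moving))
  Ff <- stats::fft(fixed - mean(fixed))
  R <- Ff * Conj(Fm)
  mag <- Mod(R)
  R <- R / pmax(mag, 1e-12)
  r <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  n <- nrow(r); m <- ncol(r)
  wrap <- function(i, k) ((i - 1) %% k) + 1
  para <- function(ym, y0, yp) {
    d <- ym - 2 * y0 + yp
    if (d == 0) 0 else 0.5 * (ym - yp) / d
  }
  dr <- para(r[wrap(pk[1] - 1, n), pk[2]], r[pk[1], pk[2]],
             r[wrap(pk[1] + 1, n), pk[2]])
  dc <- para(r[pk[1], wrap(pk[2] - 1, m)], r[pk[1], pk[2]],
             r[pk[1], wrap(pk[2] + 1, m)])
  sy <- pk[1] - 1 + dr; sx <- pk[2] - 1 + dc
  if (sy > n / 2) sy <- sy - n
  if (sx > m / 2) sx <- sx - m
  list(dy = sy, dx = sx, peak = max(r))
}

.ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

#' Estimate the rigid transform aligning `moving` onto `fixed`
#'
#' Grid search over rotation; at each candidate angle the rotated moving
#' image is registered to `fixed` by phase correlation with parabolic
#' subpixel peak interpolation, and the candidate maximizing the normalized
#' cross-correlation after warping wins.
#'
#' @param moving,fixed equal-size, non-constant real matrices.
#' @param theta_range half-range of the rotation search in degrees
#'   (default 5).
#' @param theta_step rotation grid step in degrees (default 0.1).
#' @return a [rigid_transform()] such that `warp_rigid(moving, tf)` aligns
#'   onto `fixed`.
#' @export
estimate_rigid <- function(moving, fixed, theta_range = 5, theta_step = 0.1) {
  if (!identical(dim(moving), dim(fixed)))
    stop("images must have equal dimensions", call. = FALSE)
  if (sd(moving) == 0 || sd(fixed) == 0)
    stop("images must be non-constant", call. = FALSE)
  thetas <- seq(-theta_range, theta_range, by = theta_step)
  best <- NULL; best_ncc <- -Inf; best_peak <- 0
  # coarse angle pass on a thinned grid, then fine pass around the winner
  coarse <- thetas[seq(1, length(thetas), by = max(1, floor(0.5 / theta_step)))]
  eval_theta <- function(th) {
    rot <- if (th == 0) moving else warp_rigid(moving, rigid_transform(0, 0, th))
    pc <- .phase_correlate(rot, fixed)
    tf <- rigid_transform(pc$dx, pc$dy, th)
    w <- warp_rigid(moving, tf)
    list(tf = tf, ncc = .ncc(w, fixed), peak = pc$peak)
  }
  for (th in coarse) {
    cand <- eval_theta(th)
    if (cand$ncc > best_ncc) { best <- cand$tf; best_ncc <- cand$ncc
                               best_peak <- cand$peak }
  }
  fine <- thetas[abs(thetas - best$theta) <= 0.6 & !(thetas %in% coarse)]
  for (th in fine) {
    cand <- eval_theta(th)
    if (cand$ncc > best_ncc) { best <- cand$tf; best_ncc <- cand$ncc
                               best_peak <- cand$peak }
  }
  if (best_peak < 0.1)
    stop("low-confidence registration (phase-correlation peak < 0.1)",
         call. = FALSE)
  best
}

#' Cross-register the axial zero of a hologram and a bright-field stack
#'
#' The hologram's autofocused height and the sharpest bright-field plane are
#' both declared z = 0; the returned offset, added to hologram propagation
#' distances, maps them onto the bright-field z axis.
#'
#' @param holo a preprocessed [hologram_frame()].
#' @param bf_stack a bright-field [field_stack()].
#' @param z_min,z_max hologram autofocus search range in um.
#' @param ... passed to [autofocus()].
#' @return the axial offset in um (`z_bf = z_holo + offset`).
#' @export
axial_zero_register <- function(holo, bf_stack, z_min, z_max, ...) {
  stopifnot(inherits(bf_stack, "field_stack"))
  af <- autofocus(holo, z_min, z_max, ...)
  i_bf <- stack_focus_index(bf_stack)
  bf_stack$z_list[i_bf] - af$z_star
}

#' Cut registered patch pairs from a backpropagation / bright-field stack pair
#'
#' For each z-matched plane pair the bright-field plane is rigidly registered
#' onto the backpropagated amplitude (cross-modality phase correlation on
#' mean-removed luminance), then axis-aligned patches are cropped on a
#' regular grid from both. Patches that would overlap the warped border are
#' dropped.
#'
#' @param backprop_stack a "backpropagation" [field_stack()].
#' @param bf_stack a "brightfield_gt" [field_stack()] at the same pitch and
#'   z_list.
#' @param patch patch side in px (default 256).
#' @param stride patch stride in px (default 128).
#' @param register logical: estimate and apply per-plane rigid registration
#'   (default TRUE; FALSE trusts the generator's intrinsic alignment).
#' @param theta_range rotation search half-range in degrees.
#' @return a list of pairs, each `list(input, target, z, row, col)` with
#'   `input` a complex matrix patch and `target` an RGB array patch.
#' @export
make_registered_pairs <- function(backprop_stack, bf_stack, patch = 256,
                                  stride = 128, register = TRUE,
                                  theta_range = 2) {
  stopifnot(inherits(backprop_stack, "field_stack"),
            inherits(bf_stack, "field_stack"))
  if (abs(backprop_stack$pitch - bf_stack$pitch) > 1e-9)
    stop("stacks must share a lateral pitch", call. = FALSE)
  if (length(backprop_stack) != length(bf_stack) ||
      max(abs(backprop_stack$z_list - bf_stack$z_list)) > 1e-6)
    stop("stacks must be axially registered on the same z_list",
         call. = FALSE)
  d <- dim(backprop_stack$planes[[1]])
  if (patch > min(d)) stop("patch larger than plane", call. = FALSE)
  pairs <- list()
  for (k in seq_along(backprop_stack$planes)) {
    cplane <- backprop_stack$planes[[k]]
    bplane <- bf_stack$planes[[k]]
    border <- 0
    if (register) {
      amp <- Mod(cplane)
      lum <- plane_amplitude(bplane)
      tf <- tryCatch(
        estimate_rigid(lum, amp, theta_range = theta_range),
        error = function(e) rigid_transform(0, 0, 0))
      if (abs(tf$dx) > 1e-3 || abs(tf$dy) > 1e-3 || abs(tf$theta) > 1e-3) {
        for (ch in 1:3) bplane[, , ch] <- warp_rigid(bplane[, , ch], tf)
        border <- ceiling(max(abs(tf$dx), abs(tf$dy)) +
                            sin(abs(tf$theta) * pi / 180) * max(d) / 2)
      }
    }
    r0s <- seq(1, d[1] - patch + 1, by = stride)
    c0s <- seq(1, d[2] - patch + 1, by = stride)
    for (r0 in r0s) for (c0 in c0s) {
      if (r0 <= border || c0 <= border ||
          r0 + patch - 1 > d[1] - border || c0 + patch - 1 > d[2] - border)
        next
      pairs[[length(pairs) + 1]] <- list(
        input = cplane[r0:(r0 + patch - 1), c0:(c0 + patch - 1)],
        target = bplane[r0:(r0 + patch - 1), c0:(c0 + patch - 1), ,
                        drop = FALSE],
        z = backprop_stack$z_list[k], row = r0, col = c0)
    }
  }
  if (length(pairs) == 0) stop("no valid patches", call. = FALSE)
  pairs
}
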