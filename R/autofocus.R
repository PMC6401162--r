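#' Tamura coefficient of the gradient magnitude (edge sparsity)
#'
#' The focus criterion: gradient magnitude by central differences with edge
#' replication, then sqrt(sd/mean) of that gradient image. Sharp, sparse
#' edges maximize it; a constant image scores 0. Invariant to positive
#' scaling of the image.
#'
#' @param image finite real matrix.
#' @return a nonnegative scalar; 0 when the gradient mean is 0.
#' @export
tamura_of_gradient <- function(image) {
  if (!all(is.finite(image))) stop("image must be finite", call. = FALSE)
  n <- nrow(image); m <- ncol(image)
  # central differences, edge-replicated: pad by repeating border rows/cols
  up    <- image[c(1, seq_len(n - 1)), , drop = FALSE]
  down  <- image[c(seq_len(n - 1) + 1, n), , drop = FALSE]
  left  <- image[, c(1, seq_len(m - 1)), drop = FALSE]
  right <- image[, c(seq_len(m - 1) + 1, m), drop = FALSE]
  g <- sqrt(((down - up) / 2)^2 + ((right - left) / 2)^2)
  mg <- mean(g)
  if (mg == 0) return(0)
  sqrt(sd(g) / mg)
}

# criterion value for the hologram backpropagated to height z
.focus_score <- function(holo, z, pad_factor, on = "amplitude") {
  st <- backpropagate_hologram(holo, z, pad_factor = pad_factor)
  a <- Mod(st$planes[[1]])
  if (on == "intensity") a <- a^2
  tamura_of_gradient(a)
}

#' Edge-sparsity autofocus of a hologram
#'
#' Coarse grid search over the backpropagation height followed by
#' golden-section refinement of the Tamura-of-gradient criterion evaluated on
#' the amplitude of the backpropagated field.
#'
#' @param holo a preprocessed [hologram_frame()].
#' @param z_min,z_max search range in um (`z_min < z_max`).
#' @param coarse_step coarse grid step in um (default 10).
#' @param tol refinement tolerance in um (default 0.1).
#' @param pad_factor spectral interpolation during the search (default 1:
#'   focusing does not need the refined pitch).
#' @param on criterion input, "amplitude" (default) or "intensity".
#' @return a list with `z_star` (um) and `curve`, a data.frame of the coarse
#'   focus curve (`z`, `score`).
#' @export
autofocus <- function(holo, z_min, z_max, coarse_step = 10, tol = 0.1,
                      pad_factor = 1, on = c("amplitude", "intensity")) {
  on <- match.arg(on)
  if (z_min >= z_max) stop("z_min must be < z_max", call. = FALSE)
  zs <- seq(z_min, z_max, by = coarse_step)
  if (zs[length(zs)] < z_max) zs <- c(zs, z_max)
  scores <- vapply(zs, function(z) .focus_score(holo, z, pad_factor, on),
                   numeric(1))
  if ((max(scores) - min(scores)) < 1e-6 * max(max(scores), 1e-300))
    stop("flat focus curve: no focus found", call. = FALSE)
  i <- which.max(scores)
  lo <- zs[max(1, i - 1)]; hi <- zs[min(length(zs), i + 1)]
  # golden-section maximization on [lo, hi]
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- .focus_score(holo, c1, pad_factor, on)
  f2 <- .focus_score(holo, c2, pad_factor, on)
  while ((b - a) > tol) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- .focus_score(holo, c2, pad_factor, on)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- .focus_score(holo, c1, pad_factor, on)
    }
  }
  list(z_star = (a + b) / 2,
       curve = data.frame(z = zs, score = scores))
}

#' Index of the sharpest plane in a stack
#'
#' Argmax of [tamura_of_gradient()] over plane amplitudes (luminance for RGB
#' planes); ties break toward the lower z. Used to register bright-field
#' stacks to their "zero" height.
#'
#' @param stack a [field_stack()].
#' @return 1-based index of the sharpest plane.
#' @export
stack_focus_index <- function(stack) {
  stopifnot(inherits(stack, "field_stack"))
  if (length(stack$planes) == 0) stop("empty stack", call. = FALSE)
  scores <- vapply(stack$planes,
                   function(p) tamura_of_gradient(plane_amplitude(p)),
                   numeric(1))
  which.max(scores)   # which.max returns the first (lowest-z) maximum
}
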