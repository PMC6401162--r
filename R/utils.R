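#' @useDynLib holobright, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft median quantile rnorm runif sd setNames
NULL

# All physical quantities in this package are in micrometres (um) unless a
# function documents otherwise. Grids are matrices indexed [row, col] = [y, x].

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never perturb
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Derive a reproducible substream seed from a master seed and a name
#'
#' Stable polynomial hash of the UTF-8 bytes, folded into 31 bits and
#' combined with the master seed, so every stochastic stage of a run draws
#' from its own named stream and runs are reproducible end to end.
#'
#' @param master_seed integer master seed for the run.
#' @param name character substream name (e.g. "phantom", "noise", "split").
#' @return a positive integer seed below 2^31.
#' @export
substream_seed <- function(master_seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  h <- 7
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483647
  as.integer((h + as.numeric(master_seed) * 2654435) %% 2147483647) + 1L
}

# DFT-convention frequency samples for n points at the given pitch (cycles/um)
fft_freq <- function(n, pitch) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / (n * pitch)
}

# root-mean-square of a numeric array
rms <- function(x) sqrt(mean(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
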