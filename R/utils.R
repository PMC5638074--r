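# Internal helpers shared across modules.

# Classed conditions so callers/tests can distinguish failure modes.
htr_stop <- function(subclass, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("htrcine_", subclass), "htrcine_error")))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    htr_stop("invalid_parameter", "seed must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

is_power_of_two <- function(n) {
  n == as.integer(n) && n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}

#' 2-D FFT helpers with a fixed k-space layout
#'
#' The package stores k-space in the FFT-shifted layout: the DC component sits
#' at (zero-based) index `matrix/2` along both axes, so phase-encode row 0 is
#' the most negative spatial frequency. `fft2`/`ifft2` are plain unshifted
#' transforms; `fftshift2`/`ifftshift2` move between the natural FFT layout and
#' the stored layout (identical operations for even matrix sizes).
#'
#' @param x a complex (or real) matrix.
#' @return a matrix of the same dimension.
#' @keywords internal
#' @name fft-layout
NULL

#' @rdname fft-layout
fft2 <- function(x) stats::fft(x)

#' @rdname fft-layout
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' @rdname fft-layout
fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  x[c((s1 + 1L):n1, 1L:s1), c((s2 + 1L):n2, 1L:s2), drop = FALSE]
}

#' @rdname fft-layout
ifftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  s1 <- ceiling(n1 / 2); s2 <- ceiling(n2 / 2)
  x[c((s1 + 1L):n1, 1L:s1), c((s2 + 1L):n2, 1L:s2), drop = FALSE]
}

# image -> stored (shifted) k-space
image_to_kspace <- function(img) fftshift2(fft2(img))

# stored (shifted) k-space -> complex image
kspace_to_image <- function(k) ifft2(ifftshift2(k))
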