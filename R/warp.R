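#' Sinh-arcsinh (SHASH) likelihood warp
#'
#' The warp maps an observed response `y` into a Gaussian latent variable
#' `z = sinh(b * asinh(y) - a)`. With skew `a = 0` and tail weight `b = 1`
#' it is the identity. Its inverse applied to a standard normal variate
#' yields a SHASH-distributed variable: positive `a` skews the distribution
#' to the right, `b > 1` lightens and `b < 1` heavies the tails.
#'
#' @param y Numeric vector of responses.
#' @param z Numeric vector of latent (Gaussianised) values.
#' @param a Skew parameter (real).
#' @param b Tail-weight parameter, strictly positive.
#' @return `warp()` and `warp_inverse()` return numeric vectors;
#'   `warp_deriv()` returns the strictly positive derivative dz/dy.
#' @examples
#' warp(0, a = 1, b = 1)          # sinh(-1)
#' warp_inverse(warp(2, 0.5, 0.8), 0.5, 0.8)
#' @export
warp <- function(y, a = 0, b = 1) {
  check_warp_params(a, b)
  sinh(b * asinh(y) - a)
}

#' @rdname warp
#' @export
warp_inverse <- function(z, a = 0, b = 1) {
  check_warp_params(a, b)
  sinh((asinh(z) + a) / b)
}

#' @rdname warp
#' @export
warp_deriv <- function(y, a = 0, b = 1) {
  check_warp_params(a, b)
  b * cosh(b * asinh(y) - a) / sqrt(1 + y^2)
}

check_warp_params <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L) {
    abort("warp parameters `a` and `b` must be numeric scalars")
  }
  if (!is.finite(b) || b <= 0) {
    abort("warp tail parameter `b` must be strictly positive")
  }
  invisible(TRUE)
}

#' Draw SHASH-distributed noise
#'
#' Samples `n` values from the sinh-arcsinh distribution with location 0:
#' `scale * warp_inverse(Z; a, b)` for standard-normal `Z`. With `a = 0`,
#' `b = 1` this reduces to `N(0, scale^2)`.
#'
#' @param n Number of draws.
#' @param scale Positive scale.
#' @param a,b SHASH shape parameters (see [warp()]).
#' @return Numeric vector of length `n`.
#' @export
rshash <- function(n, scale = 1, a = 0, b = 1) {
  if (!is.finite(scale) || scale <= 0) {
    abort("SHASH `scale` must be strictly positive")
  }
  check_warp_params(a, b)
  scale * warp_inverse(rnorm(n), a = a, b = b)
}
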