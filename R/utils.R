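#' Round half away from zero
#'
#' Deterministic round-half-up used at every quantization site in the
#' package (gray-level normalization, histogram equalization, tanh-to-pixel
#' mapping). Base \code{round()} rounds half to even, which would make
#' 127.5 map to 128 or 127 depending on parity; a single explicit
#' convention keeps all image quantization reproducible.
#'
#' @param x numeric vector/matrix/array.
#' @return `x` rounded to the nearest integer, halves away from zero.
#' @examples
#' roundHalfUp(c(0.5, 1.5, 2.49, -0.5))
#' @export
roundHalfUp <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Clamp values to a closed interval
#' @param x numeric.
#' @param lo,hi interval bounds.
#' @return `x` with values outside `[lo, hi]` replaced by the bound.
#' @keywords internal
clampRange <- function(x, lo, hi) {
  pmin(pmax(x, lo), hi)
}

## stop() wrapper giving errors a class so callers/tests can be specific
emgStop <- function(msg, class) {
  stop(structure(class = c(class, "emgGAN_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
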