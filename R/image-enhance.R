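#' @include AllClasses.R utils.R
NULL

#' Histogram-equalization lookup table
#'
#' Discrete histogram equalization: with `p(r_k)` the fraction of pixels
#' at gray level `r_k`, the output level for input level `k` is
#' `s_k = (L-1) * sum_{j<=k} p(r_j)`, rounded half up. The table is
#' monotone non-decreasing and the highest occupied level always maps to
#' `L-1`.
#'
#' @param img integer matrix of pixels in `[0, L-1]`.
#' @param L number of gray levels (default 256).
#' @return list of class `HistogramMapping` with `L`, `table` (integer
#'   vector of length `L`, `table[k+1]` is the output level for input
#'   level `k`) and `sourceHistogram` (the `L` estimated probabilities).
#' @examples
#' computeMapping(matrix(0:3, 2), L = 4)$table
#' @export
computeMapping <- function(img, L = 256L) {
  L <- as.integer(L)
  if (min(img) < 0 || max(img) >= L)
    emgStop(sprintf("pixels must lie in [0, %d]", L - 1L),
            "emgGAN_range_error")
  counts <- tabulate(as.integer(img) + 1L, nbins = L)
  p <- counts / length(img)
  s <- (L - 1) * cumsum(p)
  tab <- as.integer(roundHalfUp(s))
  structure(list(L = L, table = tab, sourceHistogram = p),
            class = "HistogramMapping")
}

#' Equalize one grayscale image
#'
#' Applies the image's own cumulative-distribution lookup table
#' ([computeMapping()]) pixel-wise. Equalization is per image, not over
#' the dataset.
#'
#' @param img integer matrix of pixels in `[0, L-1]`.
#' @param L number of gray levels (default 256).
#' @return integer matrix of equalized pixels.
#' @examples
#' equalizeImage(matrix(c(0L, 0L, 1L, 3L), 2), L = 4)
#' @export
equalizeImage <- function(img, L = 256L) {
  map <- computeMapping(img, L)
  out <- img
  out[] <- map$table[as.integer(img) + 1L]
  storage.mode(out) <- "integer"
  out
}

#' Equalize every image of a GrayImageSet
#'
#' @param x a [GrayImageSet].
#' @param L gray levels (default 256).
#' @return a [GrayImageSet] with equalized pixels; labels and provenance
#'   preserved, equalized flags set.
#' @export
equalizeImages <- function(x, L = 256L) {
  stopifnot(is(x, "GrayImageSet"))
  px <- x@pixels
  for (k in seq_len(nSamples(x)))
    px[, , k] <- equalizeImage(x@pixels[, , k], L)
  new("GrayImageSet", pixels = px, labels = x@labels,
      provenance = x@provenance, equalized = rep(TRUE, nSamples(x)))
}

#' Grayscale to replicated-RGB and back
#'
#' The DCGAN consumes 3-channel images: a grayscale matrix `A` is
#' replicated to `[A, A, A]`. The inverse maps an RGB array back to gray
#' by the unweighted per-pixel channel mean (rounded half up) — the three
#' channels are replicas by construction, so any convex combination is
#' equivalent and the mean is the simplest.
#'
#' @param img integer matrix (gray) for `grayToRgb`; numeric array
#'   `h x w x 3` for `rgbToGray`.
#' @return `grayToRgb`: array `h x w x 3`; `rgbToGray`: integer matrix.
#' @examples
#' rgb <- grayToRgb(matrix(0:3, 2))
#' identical(rgbToGray(rgb), matrix(0:3, 2))
#' @export
grayToRgb <- function(img) {
  array(rep(img, 3L), c(dim(img), 3L))
}

#' @rdname grayToRgb
#' @export
rgbToGray <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    emgStop("expected an h x w x 3 array", "emgGAN_shape_error")
  out <- roundHalfUp((img[, , 1, drop = FALSE] + img[, , 2, drop = FALSE] +
                        img[, , 3, drop = FALSE]) / 3)
  dim(out) <- dim(img)[1:2]
  storage.mode(out) <- "integer"
  out
}
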