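#' @include AllClasses.R utils.R
NULL

#' Reshape one EMG window into a square matrix
#'
#' Rearranges a `16 x 256` window into a `64 x 64` matrix by cutting each
#' channel's 256 time points into four consecutive rows of 64: output row
#' `r` (0-based) holds channel `floor(r/4)`'s time points
#' `64*(r mod 4) .. 64*(r mod 4)+63`. The operation is a pure
#' rearrangement (the value multiset is preserved); it generalizes to any
#' `channels x time` window whose area is a perfect square with
#' `time` a multiple of the square side.
#'
#' @param window numeric matrix, channels x time (16 x 256 by default).
#' @return numeric `side x side` matrix.
#' @examples
#' a <- matrix(seq_len(16 * 256) - 1, 16, 256, byrow = TRUE)
#' b <- reshapeWindow(a)
#' b[1, 1:4]  # first time points of channel 1
#' @export
reshapeWindow <- function(window) {
  if (!is.matrix(window))
    emgStop("window must be a matrix", "emgGAN_shape_error")
  nc <- nrow(window)
  nt <- ncol(window)
  side <- sqrt(nc * nt)
  if (side != floor(side) || nt %% side != 0)
    emgStop(sprintf("cannot reshape %d x %d window to a square", nc, nt),
            "emgGAN_shape_error")
  side <- as.integer(side)
  rowsPerCh <- nt %/% side
  ## 0-based: out[r, c] = window[r %/% rowsPerCh, side*(r %% rowsPerCh) + c];
  ## realized as one index-matrix gather so the storage mode is preserved
  r <- 0:(side - 1L)
  ch <- r %/% rowsPerCh
  off <- side * (r %% rowsPerCh)
  idx <- outer(ch + 1L, integer(side), "+") +
    (outer(off, 0:(side - 1L), "+")) * nc
  out <- window[idx]
  dim(out) <- c(side, side)
  out
}

#' Normalize a real-valued matrix to 8-bit gray levels
#'
#' Per-matrix min-max normalization to `[0, 255]`:
#' `b = 255 * (a - min(A)) / (max(A) - min(A))`, rounded half up. The
#' minimum maps to 0 and the maximum to 255; the mapping is invariant
#' under positive affine transforms of the input. A constant matrix has
#' no dynamic range: it is mapped to the all-zero image with a warning so
#' batch pipelines survive silent channels.
#'
#' @param m numeric matrix with finite entries.
#' @return integer matrix of the same shape, values in `[0, 255]`.
#' @examples
#' normalizeToGray(matrix(c(-1, 0, 1, -1), 2))
#' @export
normalizeToGray <- function(m) {
  if (!all(is.finite(m)))
    emgStop("matrix contains non-finite values", "emgGAN_value_error")
  aMin <- min(m)
  aMax <- max(m)
  if (aMax == aMin) {
    warning("degenerate matrix (max == min); returning all-zero image")
    out <- m
    out[] <- 0L
    storage.mode(out) <- "integer"
    return(out)
  }
  out <- roundHalfUp(255 * (m - aMin) / (aMax - aMin))
  storage.mode(out) <- "integer"
  out
}

#' Convert an EmgSet to grayscale images
#'
#' Composition of [reshapeWindow()] and [normalizeToGray()] over every
#' window; provenance is `"real"`, equalized flag `FALSE`.
#'
#' @param x an [EmgSet].
#' @return a [GrayImageSet].
#' @export
windowsToImages <- function(x) {
  stopifnot(is(x, "EmgSet"))
  d <- dim(x@windows)
  n <- d[3]
  side <- as.integer(sqrt(d[1] * d[2]))
  px <- array(0L, c(side, side, n))
  for (k in seq_len(n))
    px[, , k] <- normalizeToGray(reshapeWindow(x@windows[, , k]))
  new("GrayImageSet", pixels = px, labels = x@labels,
      provenance = rep("real", n), equalized = rep(FALSE, n))
}

#' Flatten an image to a classification feature vector
#'
#' Row-major flatten to length `side^2` with each feature scaled to
#' `[0, 1]` by `pixel / 255`; with a 64 x 64 image this is the 4,096-value
#' feature vector to which the class label is appended as column 4,097.
#'
#' @param img integer matrix of pixels in `[0, 255]`.
#' @return numeric vector in `[0, 1]`, length `nrow(img) * ncol(img)`.
#' @export
imageToVector <- function(img) {
  if (!is.matrix(img)) emgStop("img must be a matrix", "emgGAN_shape_error")
  ## row-major: feature[side*r + c] = img[r, c] (0-based)
  as.vector(t(img)) / 255
}

#' Vectorize a GrayImageSet into a labeled feature table
#'
#' @param x a [GrayImageSet].
#' @return list with `features` (matrix `n x side^2`, values in `[0, 1]`,
#'   columns named `px1..`) and `labels` (integer).
#' @export
imagesToVectors <- function(x) {
  stopifnot(is(x, "GrayImageSet"))
  d <- dim(x@pixels)
  n <- d[3]
  feats <- matrix(0, n, d[1] * d[2])
  for (k in seq_len(n)) feats[k, ] <- imageToVector(x@pixels[, , k])
  colnames(feats) <- paste0("px", seq_len(ncol(feats)))
  list(features = feats, labels = x@labels)
}

#' Build a GrayImageSet from a pixel array
#'
#' @param px integer array `side x side x n`.
#' @param labels integer labels (recycled if length 1).
#' @param provenance `"real"` or `"synthetic"` (recycled).
#' @param equalized logical (recycled).
#' @return a [GrayImageSet].
#' @export
grayImageSet <- function(px, labels, provenance = "real",
                         equalized = FALSE) {
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  n <- dim(px)[3]
  storage.mode(px) <- "integer"
  new("GrayImageSet", pixels = px,
      labels = rep(as.integer(labels), length.out = n),
      provenance = rep(provenance, length.out = n),
      equalized = rep(equalized, length.out = n))
}

#' Concatenate GrayImageSets
#' @param ... [GrayImageSet] objects of identical image size.
#' @return a single [GrayImageSet].
#' @export
concatImageSets <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) > 0)
  sides <- vapply(sets, function(s) dim(s@pixels)[1], 0)
  if (length(unique(sides)) != 1)
    emgStop("image sizes differ", "emgGAN_shape_error")
  px <- array(unlist(lapply(sets, function(s) s@pixels)),
              c(sides[1], sides[1], sum(vapply(sets, nSamples, 0L))))
  storage.mode(px) <- "integer"
  new("GrayImageSet", pixels = px,
      labels = unlist(lapply(sets, function(s) s@labels)),
      provenance = unlist(lapply(sets, function(s) s@provenance)),
      equalized = unlist(lapply(sets, function(s) s@equalized)))
}

#' Write / read a GrayImageSet as 8-bit grayscale PNG files
#'
#' One file per image named `<class>_<provenance>_<index>.png` (a `-eq`
#' tag is appended before the extension for equalized images).
#'
#' @param x a [GrayImageSet].
#' @param dir output directory (created if missing).
#' @return `writeImagePngs` returns the file paths invisibly;
#'   `readImagePngs` returns a [GrayImageSet] (provenance and flags parsed
#'   back from the filenames).
#' @export
writeImagePngs <- function(x, dir) {
  stopifnot(is(x, "GrayImageSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nSamples(x)
  paths <- character(n)
  for (k in seq_len(n)) {
    tag <- if (x@equalized[k]) "-eq" else ""
    paths[k] <- file.path(dir, sprintf("%d_%s_%04d%s.png", x@labels[k],
                                       x@provenance[k], k, tag))
    png::writePNG(x@pixels[, , k] / 255, paths[k])
  }
  invisible(paths)
}

#' @rdname writeImagePngs
#' @export
readImagePngs <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0)
    emgStop(sprintf("no PNG files under %s", dir), "emgGAN_io_error")
  imgs <- lapply(files, function(f) {
    p <- png::readPNG(f)
    if (length(dim(p)) == 3L) p <- p[, , 1]
    roundHalfUp(p * 255)
  })
  base <- sub("\\.png$", "", basename(files))
  parts <- strsplit(base, "_")
  labs <- vapply(parts, function(p) as.integer(p[1]), 0L)
  prov <- vapply(parts, function(p) p[2], "")
  eq <- grepl("-eq$", base)
  side <- nrow(imgs[[1]])
  px <- array(unlist(imgs), c(side, side, length(imgs)))
  storage.mode(px) <- "integer"
  new("GrayImageSet", pixels = px, labels = labs, provenance = prov,
      equalized = eq)
}

#' Export a labeled feature table as ARFF
#'
#' Writes the 4,097-column table (features in `[0, 1]` plus nominal class
#' label) in the attribute-relation text format, for cross-checking in
#' Weka-compatible tools. Requires the `foreign` package.
#'
#' @param vectors list with `features` and `labels` as returned by
#'   [imagesToVectors()].
#' @param path output `.arff` path.
#' @param relation relation name written to the header.
#' @return `path`, invisibly.
#' @export
writeArff <- function(vectors, path, relation = "emg") {
  if (!requireNamespace("foreign", quietly = TRUE))
    emgStop("the 'foreign' package is required for ARFF export",
            "emgGAN_io_error")
  df <- as.data.frame(vectors$features)
  df$class <- factor(vectors$labels)
  foreign::write.arff(df, path)
  invisible(path)
}
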