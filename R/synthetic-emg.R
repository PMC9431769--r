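#' @include AllClasses.R
NULL

#' Specification for the synthetic sEMG simulator
#'
#' Describes a class-structured synthetic surface-EMG dataset: per gesture
#' class, each channel carries zero-mean band-limited Gaussian noise whose
#' RMS amplitude equals that class's per-channel gain, plus an additive
#' white-noise floor set by `snrDb`. The container shape mirrors a typical
#' windowed multi-channel recording: 16 channels x 256 time points at an
#' assumed 1 kHz sampling rate, so each window reshapes to a 64 x 64
#' image.
#'
#' Default class profiles give class `g` unit gain on its own contiguous
#' block of channels and zero elsewhere, which makes classes separable by
#' construction (the property the evaluation harness calibrates against).
#'
#' @param nClasses number of gesture classes.
#' @param samplesPerClass windows per class (default 100, matching the
#'   per-gesture sample count the evaluation protocols assume).
#' @param nChannels number of channels (default 16).
#' @param windowLen time points per window (default 256).
#' @param classProfiles numeric matrix `nClasses x nChannels` of
#'   nonnegative RMS gains, or `NULL` for the block-structured default.
#' @param noiseBand length-2 numeric, band edges in Hz of the band-limited
#'   process at 1 kHz sampling (default `c(20, 450)`, the typical sEMG
#'   energy band); must satisfy `0 < low < high < 500`.
#' @param snrDb signal-to-noise ratio in dB of the white-noise floor
#'   relative to the mean active-channel gain (default 20).
#' @param seed integer RNG seed; identical seeds give bit-identical data.
#' @return a list of class `SyntheticEmgSpec`.
#' @examples
#' spec <- syntheticEmgSpec(nClasses = 2, samplesPerClass = 10, seed = 1)
#' emg <- simulateEmg(spec)
#' emg
#' @export
syntheticEmgSpec <- function(nClasses, samplesPerClass = 100L,
                             nChannels = 16L, windowLen = 256L,
                             classProfiles = NULL,
                             noiseBand = c(20, 450), snrDb = 20,
                             seed = 1L) {
  nClasses <- as.integer(nClasses)
  samplesPerClass <- as.integer(samplesPerClass)
  nChannels <- as.integer(nChannels)
  windowLen <- as.integer(windowLen)
  if (nClasses < 1L || samplesPerClass < 1L || nChannels < 1L ||
      windowLen < 1L)
    emgStop("counts must be positive", "emgGAN_config_error")
  side <- sqrt(nChannels * windowLen)
  if (side != floor(side))
    emgStop("nChannels * windowLen must be a perfect square (image area)",
            "emgGAN_config_error")
  if (length(noiseBand) != 2 || noiseBand[1] <= 0 ||
      noiseBand[1] >= noiseBand[2] || noiseBand[2] >= 500)
    emgStop("noiseBand must satisfy 0 < low < high < 500 Hz",
            "emgGAN_config_error")
  if (is.null(classProfiles)) {
    classProfiles <- matrix(0, nClasses, nChannels)
    block <- max(1L, nChannels %/% nClasses)
    for (g in seq_len(nClasses)) {
      lo <- (g - 1L) * block + 1L
      hi <- if (g == nClasses) nChannels else min(g * block, nChannels)
      classProfiles[g, lo:hi] <- 1
    }
  }
  classProfiles <- as.matrix(classProfiles)
  if (!all(dim(classProfiles) == c(nClasses, nChannels)))
    emgStop("classProfiles must be nClasses x nChannels",
            "emgGAN_config_error")
  if (any(classProfiles < 0))
    emgStop("amplitude gains must be nonnegative", "emgGAN_config_error")
  structure(list(nClasses = nClasses, samplesPerClass = samplesPerClass,
                 nChannels = nChannels, windowLen = windowLen,
                 classProfiles = classProfiles, noiseBand = noiseBand,
                 snrDb = snrDb, seed = as.integer(seed), fs = 1000),
            class = "SyntheticEmgSpec")
}

#' Generate a synthetic class-structured sEMG dataset
#'
#' For class `g` and channel `i`, draws white Gaussian noise, band-limits
#' it with a zero-phase 4th-order Butterworth band-pass
#' (`signal::filtfilt`, so no phase distortion), rescales the filtered
#' trace so its RMS equals `classProfiles[g, i]`, and adds a white-noise
#' floor whose RMS is `ref * 10^(-snrDb/20)` where `ref` is the mean of
#' the nonzero profile gains (1 if all gains are zero). Labels are
#' integers `0 .. nClasses-1`.
#'
#' @param spec a [syntheticEmgSpec()].
#' @return an [EmgSet] with `nClasses * samplesPerClass` windows.
#' @examples
#' emg <- simulateEmg(syntheticEmgSpec(2, 5, seed = 42))
#' dim(windows(emg))
#' @export
simulateEmg <- function(spec) {
  if (!inherits(spec, "SyntheticEmgSpec"))
    emgStop("spec must be a SyntheticEmgSpec", "emgGAN_config_error")
  set.seed(spec$seed)
  bf <- signal::butter(4, spec$noiseBand / (spec$fs / 2), type = "pass")
  nTot <- spec$nClasses * spec$samplesPerClass
  W <- array(0, c(spec$nChannels, spec$windowLen, nTot))
  gains <- spec$classProfiles
  ref <- if (any(gains > 0)) mean(gains[gains > 0]) else 1
  noiseRms <- ref * 10^(-spec$snrDb / 20)
  k <- 0L
  labs <- integer(nTot)
  for (g in seq_len(spec$nClasses)) {
    for (s in seq_len(spec$samplesPerClass)) {
      k <- k + 1L
      labs[k] <- g - 1L
      for (i in seq_len(spec$nChannels)) {
        gain <- gains[g, i]
        x <- numeric(spec$windowLen)
        if (gain > 0) {
          raw <- stats::rnorm(spec$windowLen)
          filt <- signal::filtfilt(bf, raw)
          filt <- filt - mean(filt)
          rms <- sqrt(mean(filt^2))
          if (rms > 0) x <- filt * (gain / rms)
        }
        W[i, , k] <- x + stats::rnorm(spec$windowLen, sd = noiseRms)
      }
    }
  }
  new("EmgSet", windows = W, labels = labs)
}

#' Write / read EMG windows as CSV
#'
#' One row per sample: 4,096 raw values in channel-major order (channel
#' 1's 256 time points, then channel 2, ...) followed by a final integer
#' label column, i.e. the 4,097-column layout classifiers consume.
#'
#' @param x an [EmgSet].
#' @param path CSV file path.
#' @return `writeEmgCsv` returns `path` invisibly; `readEmgCsv` returns an
#'   [EmgSet].
#' @export
writeEmgCsv <- function(x, path) {
  stopifnot(is(x, "EmgSet"))
  d <- dim(x@windows)
  n <- d[3]
  ## channel-major flatten: t(window) stacked row-wise => as.vector of the
  ## transposed slice gives ch1 t1..tT, ch2 t1..tT, ...
  m <- matrix(0, n, d[1] * d[2])
  for (k in seq_len(n)) m[k, ] <- as.vector(t(x@windows[, , k]))
  df <- as.data.frame(m)
  names(df) <- paste0("v", seq_len(ncol(m)))
  df$label <- x@labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEmgCsv
#' @param nChannels,windowLen shape to restore on read (defaults 16 x 256).
#' @export
readEmgCsv <- function(path, nChannels = 16L, windowLen = 256L) {
  df <- utils::read.csv(path)
  nc <- ncol(df)
  if (nc != nChannels * windowLen + 1L)
    emgStop(sprintf("expected %d columns, found %d",
                    nChannels * windowLen + 1L, nc), "emgGAN_format_error")
  labs <- as.integer(df[[nc]])
  m <- as.matrix(df[, -nc, drop = FALSE])
  n <- nrow(m)
  W <- array(0, c(nChannels, windowLen, n))
  for (k in seq_len(n))
    W[, , k] <- t(matrix(m[k, ], windowLen, nChannels))
  new("EmgSet", windows = W, labels = labs)
}
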