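## Fixture builders and independent oracles shared across the suite.

## A "learnable" image class: one fixed sinusoidal pattern plus bounded
## pixel noise, so a generator only has to reproduce a stable template.
makePatternImages <- function(n, seed = 1L, noise = 25L, label = 0L) {
  set.seed(seed)
  base <- matrix(as.integer(roundHalfUp(
    127 + 100 * sin(outer(1:64, 1:64, "+") / 8))), 64, 64)
  px <- array(0L, c(64, 64, n))
  for (k in seq_len(n))
    px[, , k] <- clampRange(
      base + matrix(sample(seq(-noise, noise), 64 * 64, TRUE), 64, 64),
      0, 255)
  grayImageSet(px, labels = label)
}

## Separable two-class image fixture via the EMG simulator with
## orthogonal channel profiles (class 0 on channels 1-8, class 1 on 9-16).
makeTwoClassImages <- function(samplesPerClass = 20L, seed = 1L,
                               snrDb = 20) {
  prof <- rbind(c(rep(1, 8), rep(0, 8)), c(rep(0, 8), rep(1, 8)))
  spec <- syntheticEmgSpec(nClasses = 2, samplesPerClass = samplesPerClass,
                           classProfiles = prof, snrDb = snrDb,
                           seed = seed)
  windowsToImages(simulateEmg(spec))
}

## Brute-force index-arithmetic oracle for the 16x256 -> 64x64 reshape.
reshapeOracle <- function(a) {
  out <- matrix(a[1, 1], 64, 64)   # keeps the input storage mode
  for (r in 0:63) for (cc in 0:63)
    out[r + 1, cc + 1] <- a[r %/% 4 + 1, 64 * (r %% 4) + cc + 1]
  out
}

## Brute-force CDF-transform oracle for histogram equalization: each
## pixel maps to (L-1) * P(X <= pixel), rounded half up.
cdfEqualizeOracle <- function(img, L = 256L) {
  out <- img
  v <- as.vector(img)
  for (i in seq_along(v)) out[i] <- roundHalfUp((L - 1) * mean(v <= v[i]))
  storage.mode(out) <- "integer"
  out
}

## Rank-based formulation of the same CDF transform (fast enough for
## bulk checks): count of pixels <= v equals the max-ties rank of v.
rankEqualizeOracle <- function(img, L = 256L) {
  out <- img
  out[] <- roundHalfUp((L - 1) * rank(as.vector(img), ties.method = "max") /
                         length(img))
  storage.mode(out) <- "integer"
  out
}

## Random valid discrete distribution on k points.
randomDistribution <- function(k) {
  p <- stats::runif(k)
  p / sum(p)
}
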