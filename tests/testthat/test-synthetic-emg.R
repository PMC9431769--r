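test_that("simulator is deterministic under a fixed seed", {
  spec <- syntheticEmgSpec(2, samplesPerClass = 5, seed = 7L)
  a <- simulateEmg(spec)
  b <- simulateEmg(spec)
  expect_identical(windows(a), windows(b))
  expect_identical(sampleLabels(a), sampleLabels(b))
  expect_equal(nSamples(a), 10)
})

test_that("zero-gain profiles leave only the white-noise floor", {
  prof <- matrix(0, 1, 16)
  spec <- syntheticEmgSpec(1, samplesPerClass = 20, classProfiles = prof,
                           snrDb = 20, seed = 3L)
  emg <- simulateEmg(spec)
  ## reference amplitude defaults to 1 when all gains are zero
  expectedFloor <- 10^(-20 / 20)
  rms <- sqrt(mean(windows(emg)^2))
  expect_lt(abs(rms - expectedFloor) / expectedFloor, 0.05)
})

test_that("per-channel RMS matches orthogonal class profiles", {
  prof <- rbind(c(rep(1, 8), rep(0, 8)), c(rep(0, 8), rep(1, 8)))
  spec <- syntheticEmgSpec(2, samplesPerClass = 100, classProfiles = prof,
                           snrDb = 20, seed = 11L)
  emg <- simulateEmg(spec)
  W <- windows(emg)
  labs <- sampleLabels(emg)
  for (g in 0:1) {
    sub <- W[, , labs == g, drop = FALSE]
    chRms <- sqrt(apply(sub^2, 1, mean))
    active <- which(prof[g + 1, ] > 0)
    expect_true(all(abs(chRms[active] - 1) < 0.1))
    ## inactive channels sit near the noise floor, far below the signal
    expect_true(all(chRms[-active] < 0.25))
  }
})

test_that("generated channels are near zero-mean", {
  spec <- syntheticEmgSpec(2, samplesPerClass = 10, seed = 5L)
  emg <- simulateEmg(spec)
  W <- windows(emg)
  L <- dim(W)[2]
  for (k in seq_len(dim(W)[3])) {
    m <- rowMeans(W[, , k])
    rms <- sqrt(rowMeans(W[, , k]^2))
    expect_true(all(abs(m) < 5 * rms / sqrt(L)))
  }
})

test_that("invalid simulator configurations are rejected", {
  expect_error(syntheticEmgSpec(0, 10), class = "emgGAN_config_error")
  expect_error(syntheticEmgSpec(2, 10, noiseBand = c(100, 50)),
               class = "emgGAN_config_error")
  expect_error(syntheticEmgSpec(2, 10, noiseBand = c(20, 600)),
               class = "emgGAN_config_error")
  expect_error(syntheticEmgSpec(2, 10, nChannels = 15),
               class = "emgGAN_config_error")
  expect_error(
    syntheticEmgSpec(2, 10, classProfiles = matrix(-1, 2, 16)),
    class = "emgGAN_config_error")
})

test_that("CSV round trip preserves windows, labels and column layout", {
  spec <- syntheticEmgSpec(2, samplesPerClass = 3, seed = 2L)
  emg <- simulateEmg(spec)
  path <- tempfile(fileext = ".csv")
  writeEmgCsv(emg, path)
  df <- utils::read.csv(path)
  expect_equal(ncol(df), 4097)
  ## channel-major layout: columns 1..256 are channel 1's time points
  expect_equal(as.numeric(df[1, 1:256]), windows(emg)[1, , 1])
  expect_equal(as.numeric(df[1, 257:512]), windows(emg)[2, , 1])
  back <- readEmgCsv(path)
  expect_equal(windows(back), windows(emg))
  expect_identical(sampleLabels(back), sampleLabels(emg))
})
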