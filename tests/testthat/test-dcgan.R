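test_that("adversarial losses match their closed forms and an oracle", {
  l <- ganLosses(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(unname(l["dLoss"]), 2 * log(2))
  expect_equal(unname(l["gLoss"]), log(2))
  ## perfect discriminator limit
  l2 <- ganLosses(rep(1 - 1e-9, 4), rep(1e-9, 4))
  expect_lt(unname(l2["dLoss"]), 1e-6)
  ## element-wise oracle on random probabilities
  set.seed(1)
  for (i in 1:10) {
    r <- stats::runif(8, 0.01, 0.99)
    f <- stats::runif(8, 0.01, 0.99)
    expect_equal(unname(ganLosses(r, f)["dLoss"]),
                 -sum(log(r)) / 8 - sum(log(1 - f)) / 8)
    expect_equal(unname(ganLosses(r, f)["gLoss"]), -sum(log(f)) / 8)
    expect_equal(
      unname(ganLosses(r, f, nonSaturating = FALSE)["gLoss"]),
      sum(log(1 - f)) / 8)
  }
  ## clamped probabilities keep losses finite
  expect_true(all(is.finite(ganLosses(c(0, 1), c(0, 1)))))
})

test_that("config invariants are enforced", {
  expect_error(ganConfig(epochs = 10L, snapshotStart = 8L,
                         snapshotCount = 5L), "snapshot")
  expect_error(ganConfig(batchSize = 0L), "batchSize")
  cfg <- ganConfig(epochs = 10L, snapshotStart = 6L, snapshotCount = 5L)
  expect_s4_class(cfg, "GanConfig")
})

test_that("a minimal one-epoch run produces one snapshot and loss row", {
  imgs <- makePatternImages(8, seed = 2L)
  cfg <- ganConfig(epochs = 1L, batchSize = 8L, snapshotStart = 1L,
                   snapshotCount = 1L, seed = 3L)
  gan <- trainGan(imgs, cfg)
  expect_equal(nrow(lossTrace(gan)), 1)
  expect_equal(nSamples(snapshotImages(gan)), 1)
  expect_true(all(is.finite(unlist(lossTrace(gan)[, c("dLoss", "gLoss")]))))
})

test_that("training input contracts are enforced", {
  imgs <- makePatternImages(4, seed = 2L)
  cfg <- ganConfig(epochs = 1L, batchSize = 8L, snapshotStart = 1L,
                   snapshotCount = 1L)
  expect_error(trainGan(imgs, cfg), class = "emgGAN_config_error")
  two <- makeTwoClassImages(4, seed = 1L)
  expect_error(trainGan(two, ganConfig(epochs = 1L, batchSize = 2L,
                                       snapshotStart = 1L,
                                       snapshotCount = 1L)),
               class = "emgGAN_config_error")
})

test_that("synthesize respects count, range, provenance and snapshots window", {
  imgs <- makePatternImages(8, seed = 4L)
  cfg <- ganConfig(epochs = 10L, batchSize = 8L, snapshotStart = 6L,
                   snapshotCount = 5L, seed = 5L)
  gan <- trainGan(imgs, cfg)
  none <- synthesize(gan, 0)
  expect_equal(nSamples(none), 0)
  syn <- synthesize(gan, 7, seed = 9L)
  expect_equal(nSamples(syn), 7)
  expect_true(all(pixels(syn) >= 0 & pixels(syn) <= 255))
  expect_true(all(provenance(syn) == "synthetic"))
  expect_true(all(sampleLabels(syn) == classLabel(gan)))
  ## snapshot collection returns exactly epochs 6..10
  snap <- collectSnapshotSet(gan)
  expect_equal(nSamples(snap), 5)
  expect_identical(pixels(snap), pixels(snapshotImages(gan))[, , 6:10])
  ## valid window for 20 epochs, but the model only trained 10
  bad <- ganConfig(epochs = 20L, batchSize = 8L, snapshotStart = 16L,
                   snapshotCount = 5L)
  expect_error(collectSnapshotSet(gan, bad),
               class = "emgGAN_config_error")
})

test_that("same seed and data give an identical training trajectory", {
  imgs <- makePatternImages(8, seed = 6L)
  cfg <- ganConfig(epochs = 3L, batchSize = 8L, snapshotStart = 1L,
                   snapshotCount = 3L, seed = 7L)
  g1 <- trainGan(imgs, cfg)
  g2 <- trainGan(imgs, cfg)
  expect_identical(lossTrace(g1), lossTrace(g2))
  expect_identical(pixels(snapshotImages(g1)), pixels(snapshotImages(g2)))
  expect_identical(emgGAN:::netParameters(g1@generator),
                   emgGAN:::netParameters(g2@generator))
})
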