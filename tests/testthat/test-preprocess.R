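test_that("reshape follows the four-rows-per-channel layout", {
  a <- matrix(seq_len(16 * 256) - 1, 16, 256, byrow = TRUE)
  b <- reshapeWindow(a)
  expect_equal(b[1, ], 0:63)          # channel 1, points 1-64
  expect_equal(b[2, 1], 64)           # channel 1, point 65
  expect_equal(b[64, 64], 4095)       # channel 16, point 256
  expect_equal(b[61, 1], 15 * 256)    # channel 16, point 1
})

test_that("reshape equals the index-arithmetic oracle and preserves values", {
  set.seed(1)
  for (i in 1:5) {
    a <- matrix(sample.int(10000, 16 * 256, replace = TRUE), 16, 256)
    b <- reshapeWindow(a)
    expect_identical(b, reshapeOracle(a))
    expect_identical(sort(as.vector(b)), sort(as.vector(a)))
  }
  expect_identical(reshapeWindow(matrix(0, 16, 256)), matrix(0, 64, 64))
  expect_error(reshapeWindow(matrix(0, 16, 255)),
               class = "emgGAN_shape_error")
})

test_that("gray normalization maps min to 0, max to 255, half up", {
  m <- matrix(c(-1, 0, 1, -1, 0, 1), 2, 3)
  g <- normalizeToGray(m)
  expect_identical(sort(unique(as.vector(g))), c(0L, 128L, 255L))
  expect_equal(g[m == 0][1], 128)     # 255 * 0.5 = 127.5 rounds up
  span <- matrix(0:255, 16, 16)
  expect_identical(normalizeToGray(span), matrix(0:255, 16, 16))
})

test_that("gray normalization is invariant under positive affine maps", {
  set.seed(2)
  m <- matrix(rnorm(64 * 64), 64, 64)
  g <- normalizeToGray(m)
  expect_true(min(g) == 0 && max(g) == 255)
  expect_identical(normalizeToGray(3.7 * m + 11), g)
  expect_identical(normalizeToGray(0.001 * m - 5), g)
})

test_that("constant matrices degrade to an all-zero image with a warning", {
  expect_warning(g <- normalizeToGray(matrix(4.2, 8, 8)), "degenerate")
  expect_true(all(g == 0L))
})

test_that("image vectorization is row-major, scaled to [0,1], invertible", {
  img <- matrix(0L, 64, 64)
  expect_equal(imageToVector(img), rep(0, 4096))
  img[1, 1] <- 255L
  v <- imageToVector(img)
  expect_equal(v[1], 1.0)
  set.seed(3)
  img[] <- sample(0:255, 4096, TRUE)
  v <- imageToVector(img)
  ## row-major: entry 64*r + c (0-based) is pixel [r, c]
  expect_equal(v[64 * 2 + 3 + 1], img[3, 4] / 255)
  expect_identical(matrix(as.integer(roundHalfUp(v * 255)), 64, 64,
                          byrow = TRUE), img)
})

test_that("window-to-image composition tags provenance and flags", {
  emg <- simulateEmg(syntheticEmgSpec(2, samplesPerClass = 3, seed = 4L))
  imgs <- windowsToImages(emg)
  expect_s4_class(imgs, "GrayImageSet")
  expect_equal(nSamples(imgs), 6)
  expect_true(all(provenance(imgs) == "real"))
  expect_true(all(!isEqualized(imgs)))
  expect_identical(
    pixels(imgs)[, , 1],
    normalizeToGray(reshapeWindow(windows(emg)[, , 1])))
})

test_that("PNG round trip preserves pixels, labels and tags", {
  imgs <- makeTwoClassImages(3, seed = 6L)
  eq <- equalizeImages(imgs[1:2])
  both <- concatImageSets(imgs, eq)
  dir <- tempfile()
  writeImagePngs(both, dir)
  back <- readImagePngs(dir)
  expect_equal(nSamples(back), nSamples(both))
  ## files are re-read in sorted name order; compare as label-sorted sets
  ord1 <- order(sampleLabels(both), isEqualized(both),
                apply(pixels(both), 3, sum))
  ord2 <- order(sampleLabels(back), isEqualized(back),
                apply(pixels(back), 3, sum))
  expect_identical(pixels(both)[, , ord1], pixels(back)[, , ord2])
  expect_identical(sampleLabels(both)[ord1], sampleLabels(back)[ord2])
  expect_identical(isEqualized(both)[ord1], isEqualized(back)[ord2])
})

test_that("ARFF export writes a 4097-attribute relation", {
  skip_if_not_installed("foreign")
  imgs <- makeTwoClassImages(2, seed = 8L)
  vec <- imagesToVectors(imgs)
  path <- tempfile(fileext = ".arff")
  writeArff(vec, path)
  head <- readLines(path, n = 5000)
  expect_equal(sum(grepl("^@attribute", head)), 4097)
})
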