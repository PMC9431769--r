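test_that("accuracy is percent correct", {
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(accuracy(c(1, 1, 1), c(2, 2, 2)), 0)
  expect_equal(accuracy(c(1, 1, 1, 2, 2), c(1, 1, 2, 2, 1)), 60)
  expect_error(accuracy(1:3, 1:4), class = "emgGAN_value_error")
})

test_that("deterministic split takes the first fraction of each class", {
  vec <- list(features = matrix(seq_len(200 * 4), 200, 4),
              labels = rep(0:1, each = 100))
  sp <- splitReal(vec, 0.8)
  expect_equal(length(sp$train$labels), 160)
  expect_equal(length(sp$test$labels), 40)
  expect_equal(sp$manifest[["0"]]$train, 1:80)
  expect_equal(sp$manifest[["0"]]$test, 81:100)
  expect_equal(sp$manifest[["1"]]$train, 101:180)
  ## 10 samples at f = 0.8 -> 8/2
  small <- list(features = matrix(0, 10, 2), labels = rep(0L, 10))
  sp2 <- splitReal(small, 0.8)
  expect_equal(length(sp2$train$labels), 8)
  expect_equal(length(sp2$test$labels), 2)
  expect_warning(splitReal(small, 1.0), "empty test set")
})

test_that("cross-validation folds are stratified partitions", {
  set.seed(1)
  vec <- list(features = matrix(rnorm(60 * 5), 60, 5),
              labels = rep(0:2, times = c(20, 20, 20)))
  colnames(vec$features) <- paste0("px", 1:5)
  cv <- crossValidation(vec, "rf", k = 10, seed = 3)
  expect_length(cv$foldAccuracies, 10)
  fold <- cv$manifest
  expect_true(all(table(fold) == 6))
  ## per-fold class counts deviate from the global ratio by <= 1
  tab <- table(fold, vec$labels)
  expect_true(all(abs(tab - 2) <= 1))
  expect_error(crossValidation(vec, "rf", k = 21),
               class = "emgGAN_config_error")
})

test_that("leave-one-out on a tiny fixture partitions correctly", {
  vec <- list(features = matrix(c(rnorm(8, 0), rnorm(8, 6)), 16, 1),
              labels = rep(0:1, each = 8))
  colnames(vec$features) <- "px1"
  cv <- crossValidation(vec, "svm", k = 8, seed = 1)
  expect_length(cv$foldAccuracies, 8)
  expect_true(all(table(cv$manifest) == 2))
})

test_that("the harness separates separable classes and not shuffled ones", {
  imgs <- makeTwoClassImages(50, seed = 11L)
  vec <- imagesToVectors(imgs)
  cv <- crossValidation(vec, "rf", k = 10, seed = 5)
  expect_gte(cv$mean, 95)
  ## the linear baseline stays near chance here: after per-image min-max
  ## normalization both classes share the same pixel means and differ
  ## only in dispersion, which no linear function of raw pixels sees
  cvSvm <- crossValidation(vec, "svm", k = 10, seed = 5)
  expect_lt(cvSvm$mean, 80)
  ## label shuffle: accuracy within the 95% binomial band around chance
  set.seed(42)
  shuf <- vec
  shuf$labels <- sample(shuf$labels)
  cv0 <- crossValidation(shuf, "rf", k = 10, seed = 5)
  n <- length(shuf$labels)
  band <- 100 * 1.96 * sqrt(0.25 / n)
  expect_lt(abs(cv0$mean - 50), band + 5)
})

test_that("similarity analysis reproduces the clone-fake identity", {
  imgs <- makeTwoClassImages(20, seed = 13L)
  vec <- imagesToVectors(imgs)
  sp <- splitReal(vec, 0.8)
  report <- similarityAnalysis(vec, sp$train, classifiers = c("svm", "rf"),
                               classCounts = 2, seed = 7)
  s <- evalSummary(report)
  expect_named(s, c("classifier", "nClasses", "RR", "FR", "MR",
                    "Promotion"))
  ## fakes are clones of the training half: same decisions, zero promotion
  expect_equal(s$MR, s$RR)
  expect_equal(s$Promotion, rep(0, nrow(s)))
})

test_that("noise fakes score near chance while real training stays high", {
  imgs <- makeTwoClassImages(50, seed = 17L)
  vec <- imagesToVectors(imgs)
  set.seed(3)
  noise <- list(features = matrix(runif(40 * 4096), 40, 4096),
                labels = rep(0:1, each = 20))
  colnames(noise$features) <- colnames(vec$features)
  report <- similarityAnalysis(vec, noise, classifiers = "rf",
                               classCounts = 2, seed = 9)
  s <- evalSummary(report)
  expect_gte(s$RR, 95)
  ## trained on pure noise: inside the 95% binomial band around 50%
  nTest <- 20
  halfWidth <- 100 * 1.96 * sqrt(0.25 / nTest)
  expect_lt(abs(s$FR - 50), halfWidth + 1e-9)
  expect_error(
    similarityAnalysis(vec, list(features = noise$features,
                                 labels = rep(5L, 40))),
    class = "emgGAN_config_error")
})

test_that("the six conditions have the required structure", {
  real <- makeTwoClassImages(6, seed = 19L)
  fake <- makeTwoClassImages(4, seed = 23L)
  fake@provenance[] <- "synthetic"
  conds <- buildConditions(real, fake)
  expect_named(conds, c("R", "F", "R-E", "F-E", "FR", "FR-E"))
  expect_equal(nrow(conds$FR$features),
               nrow(conds$R$features) + nrow(conds$F$features))
  expect_equal(conds$FR$labels, c(conds$R$labels, conds$F$labels))
  ## equalization changes the vectors (images are not equalization-fixed)
  expect_false(identical(conds$R$features, conds$`R-E`$features))
  expect_identical(conds$`R-E`$features,
                   imagesToVectors(equalizeImages(real))$features)
})

test_that("reports are replayable and writable", {
  imgs <- makeTwoClassImages(12, seed = 29L)
  vec <- imagesToVectors(imgs)
  conds <- list(R = vec)
  report <- crossValidationReport(conds, classifiers = "svm", k = 4,
                                  seed = 31)
  res <- evalResults(report)
  expect_equal(nrow(res), 4)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 100))
  ## replay fold 1 from the manifest bit-exactly
  fold <- splitManifests(report)[["svm|R"]]
  tr <- list(features = vec$features[fold != 1, , drop = FALSE],
             labels = vec$labels[fold != 1])
  te <- list(features = vec$features[fold == 1, , drop = FALSE],
             labels = vec$labels[fold == 1])
  fit <- emgGAN:::fitClassifier(tr$features, tr$labels, "svm", 31)
  acc <- accuracy(emgGAN:::predictClassifier(fit, te$features), te$labels)
  expect_identical(acc, res$accuracy[res$fold == 1])
  dir <- tempfile()
  paths <- writeEvalReport(report, dir, "unit")
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[1])
  expect_equal(back$accuracy, res$accuracy)
})
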