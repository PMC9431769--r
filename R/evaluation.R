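#' @include AllClasses.R preprocess.R image-enhance.R
NULL

#' Classification accuracy in percent
#'
#' @param predictions,truth vectors of equal length (factors or atomic).
#' @return `100 * correct / total`.
#' @examples
#' accuracy(c(1, 1, 0, 0, 1), c(1, 1, 1, 0, 0))  # 60
#' @export
accuracy <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    emgStop("predictions and truth differ in length", "emgGAN_value_error")
  100 * mean(as.character(predictions) == as.character(truth))
}

## "Default parameter" baselines: linear-kernel SVM with C = 1 (libsvm
## one-vs-one multiclass) and a 100-tree random forest, both seeded.
## This mirrors common Weka defaults (SMO with a degree-1 polynomial
## kernel; RandomForest with 100 trees) without claiming bit
## compatibility with Weka.
fitClassifier <- function(features, labels, classifier = c("svm", "rf"),
                          seed = 1L) {
  classifier <- match.arg(classifier)
  y <- factor(labels)
  if (nlevels(y) < 2L)
    emgStop("need at least two classes to fit a classifier",
            "emgGAN_config_error")
  if (classifier == "svm") {
    model <- e1071::svm(x = features, y = y, kernel = "linear", cost = 1,
                        scale = FALSE)
  } else {
    model <- ranger::ranger(x = features, y = y, num.trees = 100L,
                            seed = seed, num.threads = 1L)
  }
  structure(list(model = model, classifier = classifier), class = "emgClf")
}

predictClassifier <- function(fit, features) {
  if (fit$classifier == "svm")
    as.character(stats::predict(fit$model, features))
  else
    as.character(stats::predict(fit$model, data = features,
                                num.threads = 1L)$predictions)
}

#' Deterministic per-class train/test split
#'
#' Within each class, the first `ceiling(f * n)` samples (in stored
#' order) form the training part and the remainder the test part — the
#' first-80/last-20 convention of the similarity protocol. A seeded
#' random split is available with `shuffle = TRUE`.
#'
#' @param vectors list with `features` (matrix) and `labels`, as from
#'   [imagesToVectors()].
#' @param trainFraction fraction per class assigned to training
#'   (default 0.8).
#' @param shuffle randomize within-class order first (default `FALSE`).
#' @param seed seed used when `shuffle = TRUE`.
#' @return list with `train`, `test` (each `features` + `labels`) and
#'   `manifest` (per-class train/test indices into the input).
#' @export
splitReal <- function(vectors, trainFraction = 0.8, shuffle = FALSE,
                      seed = 1L) {
  labs <- vectors$labels
  if (length(labs) == 0L)
    emgStop("empty dataset", "emgGAN_config_error")
  if (trainFraction > 1 || trainFraction <= 0)
    emgStop("trainFraction must be in (0, 1]", "emgGAN_config_error")
  classes <- sort(unique(labs))
  if (shuffle) set.seed(seed)
  trainIdx <- integer(0)
  testIdx <- integer(0)
  manifest <- list()
  for (cl in classes) {
    idx <- which(labs == cl)
    if (length(idx) == 0L)
      emgStop("empty class", "emgGAN_config_error")
    if (shuffle) idx <- idx[sample.int(length(idx))]
    nTr <- ceiling(trainFraction * length(idx))
    manifest[[as.character(cl)]] <- list(train = idx[seq_len(nTr)],
                                         test = idx[-seq_len(nTr)])
    trainIdx <- c(trainIdx, idx[seq_len(nTr)])
    testIdx <- c(testIdx, idx[-seq_len(nTr)])
  }
  if (length(testIdx) == 0L)
    warning("trainFraction leaves an empty test set")
  list(train = list(features = vectors$features[trainIdx, , drop = FALSE],
                    labels = labs[trainIdx]),
       test = list(features = vectors$features[testIdx, , drop = FALSE],
                   labels = labs[testIdx]),
       manifest = manifest)
}

subsetVectors <- function(vectors, idx) {
  list(features = vectors$features[idx, , drop = FALSE],
       labels = vectors$labels[idx])
}

bindVectors <- function(a, b) {
  list(features = rbind(a$features, b$features),
       labels = c(a$labels, b$labels))
}

#' Similarity analysis: train on real, synthetic or mixed data
#'
#' For every classifier and gesture-subset size: train on (RR) the first
#' 80% of the real samples per class, (FR) all synthetic samples, and
#' (MR) their union, always testing on the held-out 20% of real samples.
#' The MR-RR gap ("promotion") measures whether synthetic data enriches
#' training; the RR-FR gap measures real/synthetic similarity. By
#' default every subset of each requested size is evaluated and
#' accuracies are averaged per size (`subsetMode = "first"` instead uses
#' the first `k` labels only).
#'
#' @param real,fake labeled vector sets (`features` + `labels`) with
#'   matching class sets.
#' @param classifiers subset of `c("svm", "rf")`.
#' @param classCounts gesture-subset sizes; default `2:nClasses` (plus
#'   the full set even for 2-class data).
#' @param trainFraction real-data train fraction (default 0.8).
#' @param subsetMode `"all"` (average over all subsets of each size) or
#'   `"first"`.
#' @param shuffle,seed split randomization (deterministic first-80
#'   split by default; the seed also fixes the RF forests).
#' @return an [EvalReport-class]; its summary has columns
#'   `classifier, nClasses, RR, FR, MR, Promotion`.
#' @export
similarityAnalysis <- function(real, fake, classifiers = c("svm", "rf"),
                               classCounts = NULL, trainFraction = 0.8,
                               subsetMode = c("all", "first"),
                               shuffle = FALSE, seed = 1L) {
  subsetMode <- match.arg(subsetMode)
  classes <- sort(unique(real$labels))
  if (!setequal(classes, unique(fake$labels)))
    emgStop("real and fake class sets differ", "emgGAN_config_error")
  if (is.null(classCounts))
    classCounts <- unique(pmin(2:max(2, length(classes)),
                               length(classes)))
  rows <- list()
  manifests <- list()
  for (clf in classifiers) {
    for (k in classCounts) {
      subsets <- if (subsetMode == "all")
        utils::combn(classes, k, simplify = FALSE)
      else
        list(classes[seq_len(k)])
      for (sub in subsets) {
        subKey <- paste(sub, collapse = "+")
        realSub <- subsetVectors(real, real$labels %in% sub)
        fakeSub <- subsetVectors(fake, fake$labels %in% sub)
        sp <- splitReal(realSub, trainFraction, shuffle = shuffle,
                        seed = seed)
        manifests[[paste(clf, k, subKey, sep = "|")]] <- sp$manifest
        trainSets <- list(RR = sp$train, FR = fakeSub,
                          MR = bindVectors(sp$train, fakeSub))
        for (cond in names(trainSets)) {
          fit <- fitClassifier(trainSets[[cond]]$features,
                               trainSets[[cond]]$labels, clf, seed)
          acc <- accuracy(predictClassifier(fit, sp$test$features),
                          sp$test$labels)
          rows[[length(rows) + 1L]] <- data.frame(
            protocol = "similarity", classifier = clf, nClasses = k,
            subset = subKey, condition = cond, fold = NA_integer_,
            accuracy = acc)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(accuracy ~ classifier + nClasses + condition,
                          results, mean)
  wide <- stats::reshape(agg, idvar = c("classifier", "nClasses"),
                         timevar = "condition", direction = "wide")
  names(wide) <- sub("^accuracy\\.", "", names(wide))
  wide$Promotion <- wide$MR - wide$RR
  wide <- wide[order(wide$classifier, wide$nClasses),
               c("classifier", "nClasses", "RR", "FR", "MR", "Promotion")]
  new("EvalReport", results = results, summary = wide,
      manifests = manifests,
      settings = list(protocol = "similarity", seed = seed,
                      trainFraction = trainFraction,
                      subsetMode = subsetMode, shuffle = shuffle,
                      classifiers = classifiers,
                      svm = "linear kernel, C=1, one-vs-one",
                      rf = "100 trees, seeded"))
}

#' Stratified k-fold cross-validation of one dataset condition
#'
#' Samples of each class are shuffled with the given seed and dealt
#' round-robin into `k` folds, so per-fold class proportions deviate from
#' the global ones by at most one sample. Each fold in turn is the test
#' set.
#'
#' @param vectors labeled vector set (`features` + `labels`).
#' @param classifier `"svm"` or `"rf"`.
#' @param k number of folds (default 10).
#' @param seed shuffling (and RF) seed.
#' @return list with `foldAccuracies` (length `k`), `mean`, `sd` and
#'   `manifest` (fold assignment per sample).
#' @export
crossValidation <- function(vectors, classifier = c("svm", "rf"),
                            k = 10L, seed = 1L) {
  classifier <- match.arg(classifier)
  k <- as.integer(k)
  labs <- vectors$labels
  minClass <- min(table(labs))
  if (k > minClass)
    emgStop(sprintf("k=%d exceeds smallest class size %d", k, minClass),
            "emgGAN_config_error")
  set.seed(seed)
  fold <- integer(length(labs))
  for (cl in sort(unique(labs))) {
    idx <- which(labs == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  accs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- subsetVectors(vectors, fold != f)
    te <- subsetVectors(vectors, fold == f)
    fit <- fitClassifier(tr$features, tr$labels, classifier, seed)
    accs[f] <- accuracy(predictClassifier(fit, te$features), te$labels)
  }
  list(foldAccuracies = accs, mean = mean(accs), sd = stats::sd(accs),
       manifest = fold)
}

#' Assemble the six dataset conditions
#'
#' Builds R (real), F (synthetic), R-E / F-E (equalized versions), FR
#' (union of R and F) and FR-E (union of the equalized versions) as
#' labeled vector sets. Equalization happens after generation, on the
#' images, before vectorization.
#'
#' @param realImages,fakeImages [GrayImageSet]s.
#' @return named list of six vector sets.
#' @export
buildConditions <- function(realImages, fakeImages) {
  stopifnot(is(realImages, "GrayImageSet"), is(fakeImages, "GrayImageSet"))
  R <- imagesToVectors(realImages)
  F_ <- imagesToVectors(fakeImages)
  RE <- imagesToVectors(equalizeImages(realImages))
  FE <- imagesToVectors(equalizeImages(fakeImages))
  list("R" = R, "F" = F_, "R-E" = RE, "F-E" = FE,
       "FR" = bindVectors(R, F_), "FR-E" = bindVectors(RE, FE))
}

#' Cross-validate every dataset condition
#'
#' Runs [crossValidation()] for each condition and classifier and
#' collects the per-fold accuracies into an [EvalReport-class] whose
#' summary holds mean and standard deviation per condition.
#'
#' @param conditions named list of vector sets, e.g. from
#'   [buildConditions()].
#' @param classifiers subset of `c("svm", "rf")`.
#' @param k folds (default 10).
#' @param seed shuffling / RF seed.
#' @return an [EvalReport-class].
#' @export
crossValidationReport <- function(conditions, classifiers = c("svm", "rf"),
                                  k = 10L, seed = 1L) {
  rows <- list()
  manifests <- list()
  for (clf in classifiers) {
    for (cond in names(conditions)) {
      cv <- crossValidation(conditions[[cond]], clf, k = k, seed = seed)
      manifests[[paste(clf, cond, sep = "|")]] <- cv$manifest
      rows[[length(rows) + 1L]] <- data.frame(
        protocol = "cross-validation", classifier = clf,
        nClasses = length(unique(conditions[[cond]]$labels)),
        subset = cond, condition = cond, fold = seq_len(k),
        accuracy = cv$foldAccuracies)
    }
  }
  results <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(results,
                                      results[c("classifier", "condition")],
                                      drop = TRUE), function(d) {
    data.frame(classifier = d$classifier[1], condition = d$condition[1],
               mean = mean(d$accuracy), sd = stats::sd(d$accuracy))
  }))
  rownames(summ) <- NULL
  summ <- summ[order(summ$classifier,
                     match(summ$condition, names(conditions))), ]
  new("EvalReport", results = results, summary = summ,
      manifests = manifests,
      settings = list(protocol = "cross-validation", k = k, seed = seed,
                      classifiers = classifiers))
}

#' Write an EvalReport to disk
#'
#' Long-format CSV of every accuracy plus a plain-text summary mirroring
#' the RR/FR/MR/Promotion (or per-condition mean ± sd) layout.
#'
#' @param report an [EvalReport-class].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return paths written, invisibly.
#' @export
writeEvalReport <- function(report, dir, prefix = "eval") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(prefix, "-results.csv"))
  txt <- file.path(dir, paste0(prefix, "-summary.txt"))
  utils::write.csv(report@results, csv, row.names = FALSE)
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(report@summary,
                                         row.names = FALSE)), con)
  invisible(c(csv, txt))
}
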