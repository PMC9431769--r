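#' @include AllClasses.R synthetic-emg.R preprocess.R image-enhance.R dcgan.R evaluation.R
NULL

#' Pipeline configuration
#'
#' One plain-list configuration object driving the end-to-end pipeline
#' (simulate -> preprocess -> train -> generate -> evaluate). Values come
#' from, in decreasing precedence: explicit arguments, a YAML config
#' file, built-in defaults. Defaults are the reduced desk scale: 2
#' gesture classes, 100 windows per class, 120 GAN epochs with the last
#' 100 snapshots kept; the full-scale settings (1000 epochs, snapshots
#' from 901) are one override away.
#'
#' @param outDir output directory for all artifacts.
#' @param configFile optional YAML file; its entries override defaults.
#' @param realDataCsv optional CSV of real windows in the 4,097-column
#'   layout (channel-major 4,096 values + label). When given, the
#'   simulate stage is skipped. A public 16-channel gesture dataset can
#'   be exported to this layout with one row per windowed sample.
#' @param nClasses,samplesPerClass,snrDb fixture-simulator settings.
#' @param epochs,snapshotStart,snapshotCount,batchSize,zDim,learningRate
#'   GAN settings (see [ganConfig()]).
#' @param gChannels,dChannels GAN widths.
#' @param trainFraction per-class fraction of real data used for GAN
#'   training and the RR/MR training split (default 0.8).
#' @param classifiers,k,classCounts,subsetMode evaluation settings.
#' @param seed global seed; per-class GAN seeds are `seed + class`.
#' @param verbose print progress.
#' @param ... additional overrides stored as-is.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(outDir = "emggan-out", configFile = NULL,
                           realDataCsv = NULL, nClasses = 2L,
                           samplesPerClass = 100L, snrDb = 20,
                           epochs = 120L, snapshotStart = NULL,
                           snapshotCount = 100L, batchSize = 32L,
                           zDim = 100L, learningRate = 2e-4,
                           gChannels = 16L, dChannels = c(16L, 32L),
                           trainFraction = 0.8,
                           classifiers = c("svm", "rf"), k = 10L,
                           classCounts = NULL,
                           subsetMode = "all", seed = 1L,
                           verbose = FALSE, ...) {
  cfg <- list(outDir = outDir, realDataCsv = realDataCsv,
              nClasses = as.integer(nClasses),
              samplesPerClass = as.integer(samplesPerClass), snrDb = snrDb,
              epochs = as.integer(epochs),
              snapshotStart = snapshotStart,
              snapshotCount = as.integer(snapshotCount),
              batchSize = as.integer(batchSize), zDim = as.integer(zDim),
              learningRate = learningRate,
              gChannels = as.integer(gChannels),
              dChannels = as.integer(dChannels),
              trainFraction = trainFraction, classifiers = classifiers,
              k = as.integer(k), classCounts = classCounts,
              subsetMode = subsetMode, seed = as.integer(seed),
              verbose = verbose, ...)
  if (!is.null(configFile)) {
    fileCfg <- yaml::read_yaml(configFile)
    supplied <- names(as.list(match.call()))[-1]
    for (nm in names(fileCfg))
      if (!nm %in% supplied) cfg[[nm]] <- fileCfg[[nm]]
  }
  if (is.null(cfg$snapshotStart))
    cfg$snapshotStart <- cfg$epochs - cfg$snapshotCount + 1L
  cfg$snapshotStart <- as.integer(cfg$snapshotStart)
  structure(cfg, class = "PipelineConfig")
}

pipelineGanConfig <- function(cfg, classSeed) {
  ganConfig(zDim = cfg$zDim, batchSize = cfg$batchSize,
            epochs = cfg$epochs, learningRate = cfg$learningRate,
            seed = classSeed, snapshotStart = cfg$snapshotStart,
            snapshotCount = cfg$snapshotCount, gChannels = cfg$gChannels,
            dChannels = cfg$dChannels)
}

## manifest: config echo + seed + sorted content hashes, path-free so two
## runs into different directories compare equal
writeManifest <- function(dir, cfg, files, stage) {
  files <- sort(files)
  hashes <- as.vector(tools::md5sum(files))
  manifest <- list(stage = stage, seed = cfg$seed,
                   config = cfg[setdiff(names(cfg),
                                        c("outDir", "realDataCsv",
                                          "configFile"))],
                   files = stats::setNames(hashes, basename(files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

readManifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"))
}

#' Pipeline stages
#'
#' Each stage reads its inputs from, and writes its artifacts under,
#' `cfg$outDir`, leaving a `manifest.json` (config echo, seed, content
#' hashes) in every artifact directory:
#' \describe{
#'   \item{`runSimulate`}{generate the synthetic fixture dataset and
#'     write `emg/emg.csv` (skipped when `realDataCsv` is set).}
#'   \item{`runPreprocess`}{windows to 64x64 grayscale PNGs under
#'     `images/real/`.}
#'   \item{`runTrainGans`}{per-class DCGAN training on the first
#'     `trainFraction` of each class; checkpoints under `gans/`, loss
#'     traces under `losses/`, per-epoch snapshots under
#'     `snapshots/<class>/`.}
#'   \item{`runGenerate`}{collect the late-epoch snapshot sets into
#'     `images/fake/`.}
#'   \item{`runEvaluate`}{similarity analysis (raw and equalized) and
#'     10-fold cross-validation over the six conditions R, F, R-E, F-E,
#'     FR, FR-E; reports under `reports/`.}
#'   \item{`runAll`}{all of the above in order.}
#' }
#'
#' @param cfg a [pipelineConfig()].
#' @return `runAll` returns (invisibly) a list with the two
#'   [EvalReport-class] objects and the artifact manifests; the other
#'   stages return their main artifact invisibly.
#' @export
runSimulate <- function(cfg) {
  spec <- syntheticEmgSpec(nClasses = cfg$nClasses,
                           samplesPerClass = cfg$samplesPerClass,
                           snrDb = cfg$snrDb, seed = cfg$seed)
  emg <- simulateEmg(spec)
  dir <- file.path(cfg$outDir, "emg")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "emg.csv")
  writeEmgCsv(emg, path)
  writeManifest(dir, cfg, path, "simulate")
  if (cfg$verbose) message("simulate: wrote ", path)
  invisible(emg)
}

#' @rdname runSimulate
#' @export
runPreprocess <- function(cfg) {
  src <- if (!is.null(cfg$realDataCsv)) cfg$realDataCsv
         else file.path(cfg$outDir, "emg", "emg.csv")
  if (!file.exists(src))
    emgStop(paste0("input CSV not found: ", src), "emgGAN_io_error")
  emg <- readEmgCsv(src)
  imgs <- windowsToImages(emg)
  dir <- file.path(cfg$outDir, "images", "real")
  paths <- writeImagePngs(imgs, dir)
  writeManifest(dir, cfg, paths, "preprocess")
  if (cfg$verbose) message("preprocess: ", length(paths), " images")
  invisible(imgs)
}

#' @rdname runSimulate
#' @export
runTrainGans <- function(cfg) {
  imgDir <- file.path(cfg$outDir, "images", "real")
  if (!dir.exists(imgDir))
    emgStop(paste0("missing image directory: ", imgDir), "emgGAN_io_error")
  imgs <- readImagePngs(imgDir)
  ganDir <- file.path(cfg$outDir, "gans")
  lossDir <- file.path(cfg$outDir, "losses")
  dir.create(ganDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lossDir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (cl in sort(unique(imgs@labels))) {
    sub <- imgs[imgs@labels == cl]
    nTr <- ceiling(cfg$trainFraction * nSamples(sub))
    gcfg <- pipelineGanConfig(cfg, cfg$seed + cl)
    gan <- trainGan(sub[seq_len(nTr)], gcfg, verbose = cfg$verbose)
    ckpt <- file.path(ganDir, sprintf("class_%d.rds", cl))
    saveRDS(gan, ckpt)
    lossCsv <- file.path(lossDir, sprintf("class_%d.csv", cl))
    utils::write.csv(gan@losses, lossCsv, row.names = FALSE)
    snapDir <- file.path(cfg$outDir, "snapshots", as.character(cl))
    snapPaths <- writeImagePngs(gan@snapshots, snapDir)
    writeManifest(snapDir, cfg, snapPaths, "snapshots")
    files <- c(files, ckpt, lossCsv)
    if (cfg$verbose) message("trained class ", cl, " on ", nTr, " images")
  }
  writeManifest(ganDir, cfg, files[grepl("\\.rds$", files)], "train")
  writeManifest(lossDir, cfg, files[grepl("\\.csv$", files)], "losses")
  invisible(files)
}

#' @rdname runSimulate
#' @export
runGenerate <- function(cfg) {
  ganDir <- file.path(cfg$outDir, "gans")
  ckpts <- list.files(ganDir, pattern = "^class_.*\\.rds$",
                      full.names = TRUE)
  if (length(ckpts) == 0L)
    emgStop(paste0("no checkpoints under ", ganDir), "emgGAN_io_error")
  sets <- lapply(sort(ckpts), function(f) collectSnapshotSet(readRDS(f)))
  fake <- do.call(concatImageSets, sets)
  dir <- file.path(cfg$outDir, "images", "fake")
  paths <- writeImagePngs(fake, dir)
  writeManifest(dir, cfg, paths, "generate")
  if (cfg$verbose) message("generate: ", length(paths), " images")
  invisible(fake)
}

#' @rdname runSimulate
#' @export
runEvaluate <- function(cfg) {
  realDir <- file.path(cfg$outDir, "images", "real")
  fakeDir <- file.path(cfg$outDir, "images", "fake")
  if (!dir.exists(realDir) || !dir.exists(fakeDir))
    emgStop("missing real or fake image directory", "emgGAN_io_error")
  real <- readImagePngs(realDir)
  fake <- readImagePngs(fakeDir)
  conds <- buildConditions(real, fake)
  simRaw <- similarityAnalysis(conds$R, conds$F,
                               classifiers = cfg$classifiers,
                               classCounts = cfg$classCounts,
                               trainFraction = cfg$trainFraction,
                               subsetMode = cfg$subsetMode,
                               seed = cfg$seed)
  simEq <- similarityAnalysis(conds$`R-E`, conds$`F-E`,
                              classifiers = cfg$classifiers,
                              classCounts = cfg$classCounts,
                              trainFraction = cfg$trainFraction,
                              subsetMode = cfg$subsetMode,
                              seed = cfg$seed)
  cv <- crossValidationReport(conds, classifiers = cfg$classifiers,
                              k = cfg$k, seed = cfg$seed)
  ## qualitative sanity logging (stochastic claims, never hard failures):
  ## a converged GAN usually gives F >= R, and equalized conditions
  ## usually match or beat their raw counterparts
  s <- cv@summary
  for (clf in unique(s$classifier)) {
    m <- function(cond) s$mean[s$classifier == clf & s$condition == cond]
    if (m("F") < m("R"))
      warning(sprintf("[%s] cross-validation accuracy of F (%.1f) below R (%.1f)",
                      clf, m("F"), m("R")))
    for (pair in list(c("R-E", "R"), c("F-E", "F"), c("FR-E", "FR")))
      if (m(pair[1]) < m(pair[2]) - 5)
        warning(sprintf("[%s] equalized condition %s (%.1f) below raw %s (%.1f)",
                        clf, pair[1], m(pair[1]), pair[2], m(pair[2])))
  }
  dir <- file.path(cfg$outDir, "reports")
  files <- c(writeEvalReport(simRaw, dir, "similarity-raw"),
             writeEvalReport(simEq, dir, "similarity-equalized"),
             writeEvalReport(cv, dir, "crossval"))
  ## split manifests, replayable
  jsonlite::write_json(list(similarityRaw = simRaw@manifests,
                            similarityEqualized = simEq@manifests,
                            crossValidation = cv@manifests),
                       file.path(dir, "splits.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  writeManifest(dir, cfg, c(files, file.path(dir, "splits.json")),
                "evaluate")
  if (cfg$verbose) message("evaluate: reports under ", dir)
  invisible(list(similarityRaw = simRaw, similarityEqualized = simEq,
                 crossValidation = cv))
}

#' @rdname runSimulate
#' @export
runAll <- function(cfg) {
  if (is.null(cfg$realDataCsv)) runSimulate(cfg)
  runPreprocess(cfg)
  runTrainGans(cfg)
  runGenerate(cfg)
  reports <- runEvaluate(cfg)
  manifests <- lapply(c(emg = "emg", real = file.path("images", "real"),
                        gans = "gans", fake = file.path("images", "fake"),
                        reports = "reports"),
                      function(d) {
    f <- file.path(cfg$outDir, d, "manifest.json")
    if (file.exists(f)) jsonlite::read_json(f) else NULL
  })
  invisible(c(reports, list(manifests = manifests)))
}
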