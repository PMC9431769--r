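#' @include AllClasses.R
NULL

#' Number of samples in a container
#' @param x an [EmgSet] or [GrayImageSet].
#' @return integer count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Gesture labels of a container
#' @param x an [EmgSet] or [GrayImageSet].
#' @return integer vector.
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname EmgSet-class
#' @param x an [EmgSet].
#' @export
setGeneric("windows", function(x) standardGeneric("windows"))

#' @rdname GrayImageSet-class
#' @param x a [GrayImageSet].
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname GrayImageSet-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname GrayImageSet-class
#' @export
setGeneric("isEqualized", function(x) standardGeneric("isEqualized"))

#' @rdname TrainedGan-class
#' @param x a [TrainedGan].
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))

#' @rdname TrainedGan-class
#' @export
setGeneric("snapshotImages", function(x) standardGeneric("snapshotImages"))

#' @rdname TrainedGan-class
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' @rdname EvalReport-class
#' @param x an [EvalReport].
#' @export
setGeneric("evalResults", function(x) standardGeneric("evalResults"))

#' @rdname EvalReport-class
#' @export
setGeneric("evalSummary", function(x) standardGeneric("evalSummary"))

#' @rdname EvalReport-class
#' @export
setGeneric("splitManifests", function(x) standardGeneric("splitManifests"))

## ---- EmgSet methods ----

#' @describeIn EmgSet-class number of windows.
#' @export
setMethod("nSamples", "EmgSet", function(x) dim(x@windows)[3])

#' @describeIn EmgSet-class gesture labels.
#' @export
setMethod("sampleLabels", "EmgSet", function(x) x@labels)

#' @describeIn EmgSet-class the `channels x time x n` array.
#' @export
setMethod("windows", "EmgSet", function(x) x@windows)

#' @describeIn EmgSet-class subset by sample index.
#' @param i sample indices.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "EmgSet", function(x, i, j, ..., drop = FALSE) {
  new("EmgSet", windows = x@windows[, , i, drop = FALSE],
      labels = x@labels[i])
})

setMethod("show", "EmgSet", function(object) {
  d <- dim(object@windows)
  cat(sprintf("EmgSet: %d windows of %d channels x %d time points\n",
              d[3], d[1], d[2]))
  if (d[3] > 0) {
    tb <- table(object@labels)
    cat("  classes:", paste(sprintf("%s (n=%d)", names(tb), tb),
                            collapse = ", "), "\n")
  }
})

## ---- GrayImageSet methods ----

#' @describeIn GrayImageSet-class number of images.
#' @export
setMethod("nSamples", "GrayImageSet", function(x) dim(x@pixels)[3])

#' @describeIn GrayImageSet-class gesture labels.
#' @export
setMethod("sampleLabels", "GrayImageSet", function(x) x@labels)

#' @describeIn GrayImageSet-class the `side x side x n` pixel array.
#' @export
setMethod("pixels", "GrayImageSet", function(x) x@pixels)

#' @describeIn GrayImageSet-class per-image provenance.
#' @export
setMethod("provenance", "GrayImageSet", function(x) x@provenance)

#' @describeIn GrayImageSet-class per-image equalized flag.
#' @export
setMethod("isEqualized", "GrayImageSet", function(x) x@equalized)

#' @describeIn GrayImageSet-class subset by image index.
#' @param i sample indices.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "GrayImageSet", function(x, i, j, ..., drop = FALSE) {
  new("GrayImageSet", pixels = x@pixels[, , i, drop = FALSE],
      labels = x@labels[i], provenance = x@provenance[i],
      equalized = x@equalized[i])
})

setMethod("show", "GrayImageSet", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("GrayImageSet: %d images of %d x %d, 8-bit\n", d[3], d[1], d[2]))
  if (d[3] > 0)
    cat(sprintf("  provenance: %s; equalized: %d of %d\n",
                paste(unique(object@provenance), collapse = "/"),
                sum(object@equalized), d[3]))
})

## ---- GanConfig / TrainedGan / EvalReport methods ----

setMethod("show", "GanConfig", function(object) {
  cat(sprintf(paste0(
    "GanConfig: z=%d, batch=%d, epochs=%d, lr=%g, beta1=%g, seed=%d\n",
    "  snapshots kept: epochs %d-%d; widths g=%d d=(%d,%d); %s g-loss\n"),
    object@zDim, object@batchSize, object@epochs, object@learningRate,
    object@beta1, object@seed, object@snapshotStart,
    object@snapshotStart + object@snapshotCount - 1L,
    object@gChannels, object@dChannels[1], object@dChannels[2],
    if (object@nonSaturating) "non-saturating" else "saturating"))
})

#' @describeIn TrainedGan-class per-epoch loss trace.
#' @export
setMethod("lossTrace", "TrainedGan", function(x) x@losses)

#' @describeIn TrainedGan-class one generated image per trained epoch.
#' @export
setMethod("snapshotImages", "TrainedGan", function(x) x@snapshots)

#' @describeIn TrainedGan-class the gesture class trained on.
#' @export
setMethod("classLabel", "TrainedGan", function(x) x@classLabel)

setMethod("show", "TrainedGan", function(object) {
  cat(sprintf(
    "TrainedGan for class %d: %d epochs, final dLoss=%.3f gLoss=%.3f\n",
    object@classLabel, nrow(object@losses),
    utils::tail(object@losses$dLoss, 1),
    utils::tail(object@losses$gLoss, 1)))
})

#' @describeIn EvalReport-class long-format per-run accuracies.
#' @export
setMethod("evalResults", "EvalReport", function(x) x@results)

#' @describeIn EvalReport-class aggregated accuracy table.
#' @export
setMethod("evalSummary", "EvalReport", function(x) x@summary)

#' @describeIn EvalReport-class split manifests (replayable indices).
#' @export
setMethod("splitManifests", "EvalReport", function(x) x@manifests)

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d accuracy rows\n", nrow(object@results)))
  if (nrow(object@summary) > 0) print(object@summary, row.names = FALSE)
})
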