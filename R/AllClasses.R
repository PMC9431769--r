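#' @import methods
NULL

#' EmgSet: a set of labeled multi-channel EMG windows
#'
#' Container for raw surface-EMG samples. Each sample is one window of
#' `nChannels x windowLen` real-valued amplitudes (the unit of
#' classification: 16 channels x 256 time points at 1 kHz by default),
#' with an integer gesture label.
#'
#' @slot windows numeric array `nChannels x windowLen x n`.
#' @slot labels integer vector of length `n`; gesture class ids.
#'
#' @seealso [simulateEmg()], [windowsToImages()], [readEmgCsv()]
#' @export
setClass("EmgSet",
  representation(windows = "array", labels = "integer"),
  validity = function(object) {
    d <- dim(object@windows)
    if (length(d) != 3L)
      return("windows must be a 3-d array (channels x time x samples)")
    if (d[3] != length(object@labels))
      return("number of samples and labels differ")
    if (!all(is.finite(object@windows)))
      return("windows contain non-finite values")
    TRUE
  })

#' GrayImageSet: a set of labeled 8-bit grayscale images
#'
#' Square grayscale images with integer pixels in `[0, 255]`, one gesture
#' label per image, plus per-image provenance (`"real"` or `"synthetic"`)
#' and an equalized flag.
#'
#' @slot pixels integer array `side x side x n`, values in `[0, 255]`.
#' @slot labels integer vector of length `n`.
#' @slot provenance character vector, `"real"` or `"synthetic"` per image.
#' @slot equalized logical vector per image.
#' @export
setClass("GrayImageSet",
  representation(pixels = "array", labels = "integer",
                 provenance = "character", equalized = "logical"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L) return("pixels must be a 3-d array")
    if (d[1] != d[2]) return("images must be square")
    n <- d[3]
    if (length(object@labels) != n) return("labels length mismatch")
    if (length(object@provenance) != n) return("provenance length mismatch")
    if (length(object@equalized) != n) return("equalized length mismatch")
    if (n > 0 && (min(object@pixels) < 0 || max(object@pixels) > 255))
      return("pixel values must lie in [0, 255]")
    if (n > 0 && !all(object@provenance %in% c("real", "synthetic")))
      return("provenance must be 'real' or 'synthetic'")
    TRUE
  })

#' GanConfig: DCGAN hyperparameters
#'
#' Hyperparameters of the per-gesture DCGAN. Defaults follow the method's
#' stated settings (batch size 32, 1000 epochs, snapshots kept from epochs
#' 901-1000) and standard DCGAN optimizer settings (Adam, learning rate
#' 2e-4, beta1 0.5). `gChannels`/`dChannels` set the free convolutional
#' widths; the generator's first fully connected stage is fixed at
#' 16 x 16 x 128 by the architecture.
#'
#' @slot zDim latent noise length (default 100).
#' @slot batchSize minibatch size (default 32).
#' @slot epochs training epochs (default 1000).
#' @slot learningRate Adam step size (default 2e-4).
#' @slot beta1,beta2 Adam moment decays (0.5, 0.999).
#' @slot seed integer RNG seed for initialization, shuffling and noise.
#' @slot snapshotStart first epoch whose snapshot enters the synthetic set
#'   (default 901).
#' @slot snapshotCount number of snapshot epochs kept (default 100).
#' @slot gChannels channel width of the generator's intermediate 32x32
#'   deconvolution output.
#' @slot dChannels integer length-2: widths of the two discriminator
#'   convolutions.
#' @slot nonSaturating logical; use the non-saturating generator loss
#'   `-log D(G(z))` (default) instead of the literal `log(1 - D(G(z)))`.
#' @slot leakyRelu logical; insert LeakyReLU(0.2) after the discriminator
#'   convolutions (off by default: the stated stack has no activation
#'   there).
#' @slot epsilon clamp inside the log losses (default 1e-7).
#' @export
setClass("GanConfig",
  representation(zDim = "integer", batchSize = "integer", epochs = "integer",
                 learningRate = "numeric", beta1 = "numeric",
                 beta2 = "numeric", seed = "integer",
                 snapshotStart = "integer", snapshotCount = "integer",
                 gChannels = "integer", dChannels = "integer",
                 nonSaturating = "logical", leakyRelu = "logical",
                 epsilon = "numeric"),
  validity = function(object) {
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (object@epochs < 1L) return("epochs must be >= 1")
    if (object@snapshotStart < 1L) return("snapshotStart must be >= 1")
    if (object@snapshotCount < 0L) return("snapshotCount must be >= 0")
    if (object@snapshotStart + object@snapshotCount - 1L > object@epochs)
      return("snapshot window [snapshotStart, snapshotStart+snapshotCount-1] exceeds epochs")
    if (length(object@dChannels) != 2L)
      return("dChannels must have length 2")
    if (object@learningRate <= 0) return("learningRate must be positive")
    TRUE
  })

#' TrainedGan: a per-gesture trained DCGAN
#'
#' Holds the generator and discriminator parameter stacks after training
#' on one gesture class, the per-epoch snapshot images (one generated
#' image per epoch from a fixed probe noise vector), and the loss trace.
#'
#' @slot classLabel the gesture class the model was trained on.
#' @slot generator,discriminator parameter stacks (lists of layers).
#' @slot snapshots [GrayImageSet] with one image per trained epoch.
#' @slot losses data.frame with columns `epoch`, `dLoss`, `gLoss`.
#' @slot config the [GanConfig] used.
#' @export
setClass("TrainedGan",
  representation(classLabel = "integer", generator = "list",
                 discriminator = "list", snapshots = "GrayImageSet",
                 losses = "data.frame", config = "GanConfig"),
  validity = function(object) {
    if (nrow(object@losses) != dim(object@snapshots@pixels)[3])
      return("one snapshot per trained epoch is required")
    if (nrow(object@losses) > 0 &&
        !all(is.finite(object@losses$dLoss)) ||
        !all(is.finite(object@losses$gLoss)))
      return("loss trace contains non-finite values")
    TRUE
  })

#' EvalReport: classifier-based evaluation results
#'
#' Long-format accuracies from the similarity-analysis and
#' cross-validation protocols, together with the split manifests needed to
#' replay any split and an echo of the settings (seeds, classifier
#' parameters).
#'
#' @slot results data.frame, one row per (protocol, classifier, condition,
#'   subset/fold) accuracy in percent.
#' @slot summary data.frame, aggregated view (e.g. RR/FR/MR columns with
#'   the MR-RR promotion, or per-condition cross-validation means).
#' @slot manifests list of split manifests (sample indices per partition).
#' @slot settings list; config echo.
#' @export
setClass("EvalReport",
  representation(results = "data.frame", summary = "data.frame",
                 manifests = "list", settings = "list"),
  validity = function(object) {
    if (nrow(object@results) > 0 &&
        (min(object@results$accuracy) < 0 || max(object@results$accuracy) > 100))
      return("accuracies must lie in [0, 100]")
    TRUE
  })
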