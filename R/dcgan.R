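#' @include AllClasses.R nn.R image-enhance.R preprocess.R
NULL

#' Construct a GanConfig
#'
#' @param zDim latent noise length (default 100).
#' @param batchSize minibatch size (default 32).
#' @param epochs training epochs (default 1000).
#' @param learningRate Adam step size (default 2e-4).
#' @param beta1,beta2 Adam moment decays (0.5, 0.999).
#' @param seed integer RNG seed.
#' @param snapshotStart first epoch kept in the synthetic snapshot set
#'   (default 901: the last 100 of 1000 epochs).
#' @param snapshotCount number of snapshot epochs kept (default 100).
#' @param gChannels generator intermediate (32x32) deconvolution width
#'   (default 8).
#' @param dChannels discriminator convolution widths (default
#'   `c(8L, 16L)`).
#' @param nonSaturating use `-log D(G(z))` for the generator (default
#'   `TRUE`); `FALSE` selects the literal `log(1 - D(G(z)))` form.
#' @param leakyRelu insert LeakyReLU(0.2) after discriminator
#'   convolutions (default `FALSE`; the canonical stack has no activation
#'   there).
#' @param epsilon log-loss clamp (default 1e-7).
#' @return a validated [GanConfig-class] object.
#' @examples
#' ganConfig(epochs = 10L, snapshotStart = 6L, snapshotCount = 5L)
#' @export
ganConfig <- function(zDim = 100L, batchSize = 32L, epochs = 1000L,
                      learningRate = 2e-4, beta1 = 0.5, beta2 = 0.999,
                      seed = 1L, snapshotStart = 901L,
                      snapshotCount = 100L, gChannels = 8L,
                      dChannels = c(8L, 16L), nonSaturating = TRUE,
                      leakyRelu = FALSE, epsilon = 1e-7) {
  new("GanConfig", zDim = as.integer(zDim),
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      learningRate = learningRate, beta1 = beta1, beta2 = beta2,
      seed = as.integer(seed), snapshotStart = as.integer(snapshotStart),
      snapshotCount = as.integer(snapshotCount),
      gChannels = as.integer(gChannels), dChannels = as.integer(dChannels),
      nonSaturating = nonSaturating, leakyRelu = leakyRelu,
      epsilon = epsilon)
}

#' Build the generator network
#'
#' Nine-layer generator: (1) fully connected from the latent vector to
#' 16x16x128 = 32,768 units, (2) batch norm, (3) tanh, (4) reshape to
#' 16x16x128, (5) transposed convolution kernel 5 stride 2 to
#' 32x32x`gChannels`, (6) tanh, (7) batch norm, (8) transposed
#' convolution kernel 5 stride 2 to 64x64x3, (9) tanh. Output values lie
#' in `[-1, 1]`.
#'
#' @param cfg a [ganConfig()].
#' @param seed RNG seed for weight initialization (default `cfg@seed`).
#' @return a network usable with [networkForward()].
#' @export
buildGenerator <- function(cfg = ganConfig(), seed = cfg@seed) {
  set.seed(seed)
  g <- cfg@gChannels
  newNet(list(
    newDense(cfg@zDim, 16L * 16L * 128L),
    newBnDense(16L * 16L * 128L),
    newAct("tanh"),
    newReshape(16L, 16L, 128L),
    newTconv(16L, 16L, 128L, g),
    newAct("tanh"),
    newBnConv(g),
    newTconv(32L, 32L, g, 3L),
    newAct("tanh")))
}

#' Build the discriminator network
#'
#' Ten-layer discriminator on 64x64x3 input: (1) convolution kernel 5
#' stride 2, (2) batch norm, (3) convolution kernel 5 stride 2, (4) batch
#' norm, (5) flatten, (6) fully connected to 1024 units, (7) batch norm,
#' (8) tanh, (9) fully connected to 1 unit, (10) sigmoid. The output is a
#' realness probability strictly inside (0, 1). With
#' `cfg@leakyRelu = TRUE` a LeakyReLU(0.2) follows each convolution (off
#' by default).
#'
#' @inheritParams buildGenerator
#' @return a network usable with [networkForward()].
#' @export
buildDiscriminator <- function(cfg = ganConfig(), seed = cfg@seed) {
  set.seed(seed)
  d1 <- cfg@dChannels[1]
  d2 <- cfg@dChannels[2]
  layers <- list(newConv(64L, 64L, 3L, d1))
  if (cfg@leakyRelu) layers <- c(layers, list(newAct("lrelu")))
  layers <- c(layers, list(newBnConv(d1), newConv(32L, 32L, d1, d2)))
  if (cfg@leakyRelu) layers <- c(layers, list(newAct("lrelu")))
  layers <- c(layers, list(
    newBnConv(d2),
    newFlatten(),
    newDense(16L * 16L * d2, 1024L),
    newBnDense(1024L),
    newAct("tanh"),
    newDense(1024L, 1L),
    newAct("sigmoid")))
  newNet(layers)
}

#' Adversarial losses from discriminator probabilities
#'
#' Discriminator loss `-mean(log D(x)) - mean(log(1 - D(G(z))))` and
#' generator loss in the non-saturating form `-mean(log D(G(z)))`
#' (default) or the literal minimax form `mean(log(1 - D(G(z))))`.
#' Probabilities are clamped to `[epsilon, 1 - epsilon]` inside the logs
#' so degenerate discriminator outputs cannot produce infinities.
#'
#' @param dReal,dFake discriminator probabilities on real and generated
#'   batches.
#' @param epsilon clamp (default 1e-7).
#' @param nonSaturating generator-loss form (default `TRUE`).
#' @return named numeric vector with elements `dLoss` and `gLoss`.
#' @examples
#' ganLosses(c(0.5, 0.5), c(0.5, 0.5))  # dLoss = 2 log 2
#' @export
ganLosses <- function(dReal, dFake, epsilon = 1e-7, nonSaturating = TRUE) {
  r <- clampRange(dReal, epsilon, 1 - epsilon)
  f <- clampRange(dFake, epsilon, 1 - epsilon)
  dLoss <- -mean(log(r)) - mean(log(1 - f))
  gLoss <- if (nonSaturating) -mean(log(f)) else mean(log(1 - f))
  c(dLoss = dLoss, gLoss = gLoss)
}

## map generator tanh output in [-1,1] to one 8-bit grayscale matrix
tensorToGray <- function(t3) {
  px <- clampRange(roundHalfUp((t3 + 1) * 127.5), 0, 255)
  rgbToGray(px)
}

#' Train a DCGAN on one gesture class
#'
#' Alternating updates over shuffled minibatches: each step first updates
#' the discriminator on a real batch and a freshly generated batch
#' (gradients of the two passes accumulate), then updates the generator
#' through the updated, frozen discriminator on the same fake batch
#' (the standard DCGAN update order). Images enter the
#' discriminator replicated to three channels and rescaled from
#' `[0, 255]` to `[-1, 1]`. After each epoch one snapshot image is
#' generated from a fixed probe noise vector (running batch-norm
#' statistics), giving one synthetic candidate per epoch. The run is
#' reproducible for a fixed seed on one machine/BLAS; bitwise identity
#' across numerics backends is not promised.
#'
#' @param images a [GrayImageSet] holding one class (at least
#'   `cfg@batchSize` images; each epoch runs over `n %/% batchSize` full
#'   minibatches of a fresh shuffle — the trailing partial batch is
#'   dropped because batch statistics on small remainders destabilize
#'   the batch-norm layers).
#' @param cfg a [ganConfig()].
#' @param verbose print a progress line every 50 epochs.
#' @return a [TrainedGan-class].
#' @export
trainGan <- function(images, cfg = ganConfig(), verbose = FALSE) {
  stopifnot(is(images, "GrayImageSet"))
  validObject(cfg)
  n <- nSamples(images)
  if (n < cfg@batchSize)
    emgStop(sprintf("need at least batchSize=%d images, got %d",
                    cfg@batchSize, n), "emgGAN_config_error")
  lab <- unique(images@labels)
  if (length(lab) != 1L)
    emgStop("trainGan expects images of a single class",
            "emgGAN_config_error")
  side <- dim(images@pixels)[1]
  if (side != 64L)
    emgStop("the DCGAN consumes 64 x 64 images", "emgGAN_shape_error")

  ## real data as 64 x 64 x 3 x n in [-1, 1]
  xAll <- array(0, c(64L, 64L, 3L, n))
  for (k in seq_len(n)) {
    g <- images@pixels[, , k] / 127.5 - 1
    xAll[, , , k] <- grayToRgb(g)
  }

  set.seed(cfg@seed)
  G <- buildGenerator(cfg, seed = cfg@seed)
  D <- buildDiscriminator(cfg, seed = cfg@seed + 1L)
  set.seed(cfg@seed + 2L)  # training stream, independent of init
  probeZ <- matrix(stats::rnorm(cfg@zDim), cfg@zDim, 1L)
  eps <- cfg@epsilon

  snaps <- array(0L, c(64L, 64L, cfg@epochs))
  losses <- data.frame(epoch = seq_len(cfg@epochs), dLoss = NA_real_,
                       gLoss = NA_real_)

  nSteps <- n %/% cfg@batchSize   # partial minibatches are dropped:
                                  # batch statistics on small remainders
                                  # destabilize the batch-norm layers
  for (ep in seq_len(cfg@epochs)) {
    perm <- sample.int(n)
    dAcc <- gAcc <- 0
    nb <- 0L
    for (s in seq_len(nSteps)) {
      idx <- perm[((s - 1L) * cfg@batchSize + 1L):(s * cfg@batchSize)]
      m <- length(idx)
      xb <- xAll[, , , idx, drop = FALSE]

      ## --- discriminator step: real batch + fresh fake batch ---
      z <- matrix(stats::rnorm(cfg@zDim * m), cfg@zDim, m)
      fw <- networkForward(G, z, train = TRUE)
      G <- fw$net
      fake <- fw$out
      D <- zeroGrads(D)
      fr <- networkForward(D, xb, train = TRUE)
      D <- fr$net
      yR <- as.vector(fr$out)
      dyR <- matrix(-1 / (m * pmax(yR, eps)), 1L, m)
      D <- netBackward(D, dyR)$net
      ff <- networkForward(D, fake, train = TRUE)
      D <- ff$net
      yF <- as.vector(ff$out)
      dyF <- matrix(1 / (m * pmax(1 - yF, eps)), 1L, m)
      D <- netBackward(D, dyF)$net
      D <- adamStep(D, cfg@learningRate, cfg@beta1, cfg@beta2)

      ## --- generator step through the updated, frozen discriminator,
      ##     reusing the same fake batch ---
      df <- networkForward(D, fake, train = TRUE)
      D <- df$net
      yF2 <- as.vector(df$out)
      D <- zeroGrads(D)
      G <- zeroGrads(G)
      dy2 <- if (cfg@nonSaturating)
        matrix(-1 / (m * pmax(yF2, eps)), 1L, m)
      else
        matrix(-1 / (m * pmax(1 - yF2, eps)), 1L, m)
      bd <- netBackward(D, dy2)
      D <- bd$net
      G <- netBackward(G, bd$dx)$net
      G <- adamStep(G, cfg@learningRate, cfg@beta1, cfg@beta2)

      ls <- ganLosses(yR, yF, eps, cfg@nonSaturating)
      gl <- ganLosses(yR, yF2, eps, cfg@nonSaturating)["gLoss"]
      dAcc <- dAcc + ls["dLoss"]
      gAcc <- gAcc + gl
      nb <- nb + 1L
    }
    losses$dLoss[ep] <- dAcc / nb
    losses$gLoss[ep] <- gAcc / nb
    if (!is.finite(losses$dLoss[ep]) || !is.finite(losses$gLoss[ep]))
      emgStop(sprintf("non-finite loss at epoch %d (d=%g, g=%g)", ep,
                      losses$dLoss[ep], losses$gLoss[ep]),
              "emgGAN_training_error")

    ## per-epoch snapshot from the fixed probe vector
    sn <- networkForward(G, probeZ, train = FALSE)$out
    snaps[, , ep] <- tensorToGray(sn[, , , 1])

    if (verbose && ep %% 50L == 0L)
      message(sprintf("epoch %d/%d  dLoss=%.3f  gLoss=%.3f", ep,
                      cfg@epochs, losses$dLoss[ep], losses$gLoss[ep]))
  }

  snapSet <- new("GrayImageSet", pixels = snaps,
                 labels = rep(lab, cfg@epochs),
                 provenance = rep("synthetic", cfg@epochs),
                 equalized = rep(FALSE, cfg@epochs))
  new("TrainedGan", classLabel = lab, generator = stripCaches(G),
      discriminator = stripCaches(D), snapshots = snapSet,
      losses = losses, config = cfg)
}

#' Generate synthetic images from a trained generator
#'
#' Draws `n` fresh latent vectors, runs the generator in evaluation mode
#' (running batch-norm statistics), maps the tanh output from `[-1, 1]`
#' to `[0, 255]` by `(v + 1) * 127.5` rounded half up, and collapses the
#' replicated RGB channels back to grayscale.
#'
#' @param gan a [TrainedGan-class].
#' @param n number of images.
#' @param seed RNG seed for the latent draws.
#' @return a [GrayImageSet] with provenance `"synthetic"`.
#' @export
synthesize <- function(gan, n, seed = 1L) {
  stopifnot(is(gan, "TrainedGan"))
  if (nrow(gan@losses) == 0L)
    emgStop("generator has not been trained", "emgGAN_state_error")
  n <- as.integer(n)
  if (n == 0L)
    return(new("GrayImageSet", pixels = array(0L, c(64L, 64L, 0L)),
               labels = integer(0), provenance = character(0),
               equalized = logical(0)))
  set.seed(seed)
  cfg <- gan@config
  px <- array(0L, c(64L, 64L, n))
  G <- gan@generator
  done <- 0L
  while (done < n) {
    m <- min(64L, n - done)
    z <- matrix(stats::rnorm(cfg@zDim * m), cfg@zDim, m)
    fw <- networkForward(G, z, train = FALSE)
    G <- fw$net
    for (k in seq_len(m))
      px[, , done + k] <- tensorToGray(fw$out[, , , k])
    done <- done + m
  }
  new("GrayImageSet", pixels = px, labels = rep(gan@classLabel, n),
      provenance = rep("synthetic", n), equalized = rep(FALSE, n))
}

#' Collect the late-epoch snapshot set
#'
#' Returns the per-epoch snapshot images from epochs
#' `snapshotStart .. snapshotStart + snapshotCount - 1` — with the
#' defaults, the last 100 of 1000 epochs, which form the synthetic
#' dataset for evaluation.
#'
#' @param gan a [TrainedGan-class].
#' @param cfg a [GanConfig-class]; defaults to the one used in training.
#' @return a [GrayImageSet].
#' @export
collectSnapshotSet <- function(gan, cfg = gan@config) {
  stopifnot(is(gan, "TrainedGan"))
  nEp <- nrow(gan@losses)
  idx <- seq(cfg@snapshotStart, length.out = cfg@snapshotCount)
  if (cfg@snapshotCount < 1L || max(idx) > nEp)
    emgStop(sprintf(
      "snapshot window %d..%d outside trained epochs 1..%d",
      cfg@snapshotStart, cfg@snapshotStart + cfg@snapshotCount - 1L, nEp),
      "emgGAN_config_error")
  gan@snapshots[idx]
}

#' Score images with a trained discriminator
#'
#' Runs the discriminator in evaluation mode on grayscale images
#' (replicated to RGB and rescaled to `[-1, 1]`).
#'
#' @param gan a [TrainedGan-class] (or a raw discriminator network).
#' @param images a [GrayImageSet].
#' @return numeric vector of realness probabilities in (0, 1).
#' @export
discriminatorScore <- function(gan, images) {
  D <- if (is(gan, "TrainedGan")) gan@discriminator else gan
  n <- nSamples(images)
  x <- array(0, c(64L, 64L, 3L, n))
  for (k in seq_len(n))
    x[, , , k] <- grayToRgb(images@pixels[, , k] / 127.5 - 1)
  as.vector(networkForward(D, x, train = FALSE)$out)
}
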