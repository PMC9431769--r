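---
title: "Methods: DCGAN-based data enhancement for multi-channel sEMG"
author: "emgGAN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DCGAN-based data enhancement for multi-channel sEMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Surface electromyography (sEMG) classifiers for hand-gesture recognition
are chronically data-limited: acquisition needs instrumented sessions,
ethics approval and patient time, so per-gesture sample counts are often
in the low hundreds. emgGAN implements a data-enhancement route around
that bottleneck: encode each multi-channel sEMG window as a small
grayscale image, train one deep convolutional generative adversarial
network (DCGAN) per gesture class on those images, and treat the
generator's outputs as additional training samples. Whether the
synthetic samples are any good is judged not by visual quality metrics
but by classification behavior — the method's own figure of merit.

## From windows to images

The unit of classification is one window of 16 channels x 256 time
points sampled at 1 kHz. `reshapeWindow()` rearranges the 16 x 256
matrix into 64 x 64 by cutting each channel's 256 points into four
consecutive rows of 64, so channel `i` occupies output rows
`4i-3 .. 4i`. The operation is a pure permutation of entries.
`normalizeToGray()` then maps the window linearly onto gray levels,
`b = 255 (a - min A) / (max A - min A)`, per image (the min and max are
those of the individual window, not of the dataset; this makes every
image span the full dynamic range but also discards absolute amplitude —
see *Limitations*). For classification, images are flattened row-major
to 4,096 features scaled to `[0, 1]`, plus the label as column 4,097.

Quantization everywhere in the package rounds half **away from zero**
(`roundHalfUp()`): base R's round-half-even would make results depend on
value parity at exact halves (255 * 0.5 = 127.5 must always give 128).
A constant window has no dynamic range; it becomes the all-zero image
with a warning rather than an error, so batch pipelines survive silent
channels.

## Histogram equalization

`equalizeImage()` applies the discrete cumulative-distribution
transform: with `p(r_k)` the fraction of pixels at level `k`, level `k`
maps to `s_k = (L - 1) * sum_{j<=k} p(r_j)`, rounded half up, with
`L = 256`. The mapping is monotone, the top occupied level always maps
to `L - 1`, and equalization is computed **per image**. In the pipeline
it is applied *after* generation: the GANs are trained on raw
(non-equalized) images, and the equalized conditions (`R-E`, `F-E`,
`FR-E`) are produced by equalizing real and generated images afterward.

The generator consumes and emits three-channel images; grayscale images
are replicated `[A, A, A]` on the way in (`grayToRgb()`) and collapsed
by the unweighted per-pixel channel mean on the way out (`rgbToGray()`).
Since the channels are replicas by construction, any convex combination
is equivalent; the mean is the simplest.

## The adversarial model

The generator and discriminator play the standard minimax game: the
discriminator maximizes `E[log D(x)] + E[log(1 - D(G(z)))]`, the
generator fools it. Two toy-scale helpers expose the equilibrium theory
used as test oracles: `optimalDiscriminator(a, b) = a/(a+b)` (the
pointwise maximizer of `a log y + b log(1-y)`), and
`cOfG(p, q) = -log 4 + 2 JS(p || q)`, the generator criterion at the
optimal discriminator, minimized exactly when the generator matches the
data distribution. These are documentation-grade mathematics, not part
of training.

### Architecture

The generator has nine layers: fully connected from the latent vector
(`zDim = 100`, `z ~ N(0, I)`) to 16 x 16 x 128 = 32,768 units, batch
norm, tanh, reshape, transposed convolution (kernel 5, stride 2) to
32 x 32, tanh, batch norm, transposed convolution to 64 x 64 x 3, tanh.
The discriminator has ten: two stride-2 kernel-5 convolutions each
followed by batch norm, flatten, fully connected to 1,024, batch norm,
tanh, fully connected to 1, sigmoid. Deliberate fidelity choices:

* the discriminator uses **tanh** at layer 8 and **no activation after
  its convolutions** — LeakyReLU is the DCGAN convention, but this stack
  keeps the stated design; a `leakyRelu` switch exists for stability
  experiments;
* the 16 x 16 x 128 figure is read as the fully connected layer's
  *output* size (reshaped at layer 4); the latent dimension is `zDim`;
* the free convolution widths (nothing fixes them except the 128-channel
  entry point and the 3-channel output) default to 8 intermediate
  generator channels and 8/16 discriminator channels. These compact
  widths are a deliberate desk-scale choice: they keep a full per-class
  training run in CPU minutes while leaving the mandated layer structure
  intact, and they are plenty of capacity for 64 x 64 single-template
  image classes. Wider settings are one `ganConfig()` argument away.

### Training

`trainGan()` trains one model per gesture class on the first 80% of
that class's images (`batchSize = 32`, `epochs = 1000` at full scale).
Each step updates the discriminator on a real minibatch and a freshly
generated minibatch (gradients of both passes accumulate), then updates
the generator through the updated, frozen discriminator on the same
fake batch — the standard DCGAN update order. Optimizer settings are
the standard DCGAN ones (Adam, learning rate 2e-4, beta1 = 0.5), and
weights initialize from N(0, 0.02). The generator loss defaults to the
non-saturating `-log D(G(z))`; the literal `log(1 - D(G(z)))` form is
available via `nonSaturating = FALSE`.

Numerical choices: probabilities are clamped at `1e-7` inside the log
losses; batch-norm uses eps 1e-5 and running-statistics momentum 0.1
(running statistics are used for all evaluation-mode passes, including
snapshots and `synthesize()`); "same" padding for kernel 5 / stride 2
pads 1 before and 2 after each spatial dimension; trailing partial
minibatches are dropped each epoch (batch statistics on remainders of a
few samples destabilize batch norm). Non-finite losses abort with a
diagnostic rather than training through a collapse.

After every epoch one snapshot image is generated from a fixed probe
noise vector, so an `epochs`-long run yields `epochs` synthetic
candidates; `collectSnapshotSet()` keeps the last `snapshotCount` of
them (epochs 901–1000 at full scale) as the synthetic dataset.
Per-class seeds are derived as `seed + class` so class runs are
independent but reproducible. Determinism is per machine/BLAS:
identical seeds give bit-identical runs on one backend; bitwise
identity across numerics libraries is not promised.

### Why the network core is written here

No deep-learning framework is part of this package's dependency
surface. The layers the architecture needs — dense, batch norm, tanh,
sigmoid, stride-2 convolution and its exact adjoint as the transposed
convolution — are implemented in `R/nn.R` on top of BLAS matrix
products, with convolutions realized as precomputed-index im2col /
col2im gathers. Two small C++ kernels (a fused in-place Adam update and
the col2im scatter-add) remove the R-level hot loops. Backpropagation
is verified against central finite differences layer by layer, and the
convolution against a direct sliding-window oracle, in the test suite.

## The synthetic fixture generator

`simulateEmg()` exists so every downstream stage is testable without
external recordings. Per class and channel it draws white Gaussian
noise, band-limits it with a zero-phase 4th-order Butterworth band-pass
(20–450 Hz at 1 kHz — the typical sEMG energy band; `filtfilt` avoids
phase distortion), rescales to the class's per-channel RMS gain, and
adds a white-noise floor at `snrDb` (default 20 dB) relative to the
mean active gain. Default class profiles give each class unit gain on
its own contiguous channel block, i.e. classes differ in *where* energy
sits.

What this emulates: the container shape, class-dependent second-order
structure, realistic band-limited spectra, a noise floor. What it does
**not** emulate: motor-unit physiology, inter-subject and inter-day
drift, electrode artifacts, amplitude non-stationarity within a window.
Passing tests on this fixture therefore demonstrate that the machinery
is correct and calibrated, not that any particular accuracy will be
reached on real recordings.

One property of the fixture deserves emphasis: band-limited noise is
symmetric and zero-mean, so after per-image min-max normalization both
classes have essentially identical pixel *means* and differ only in
dispersion. A linear SVM on raw pixels is therefore blind on this
fixture (it sits near chance), while the random-forest baseline — which
thresholds individual pixels — separates the classes almost perfectly.
The harness calibration checks consequently use the forest as the
known-answer oracle and record the linear baseline's chance-level
behavior as expected.

## Evaluation protocols

Both baselines deliberately use fixed "default" settings, mirroring
common packaged-classifier defaults rather than tuned models: a
linear-kernel SVM with `C = 1` (libsvm's one-vs-one multiclass) and a
100-tree random forest (`ranger`, seeded, single-threaded so runs are
reproducible). No feature extraction and no hyperparameter search, by
design.

**Similarity analysis** (`similarityAnalysis()`): per classifier and
class-subset size, train on (RR) the first 80% of real samples per
class, (FR) all synthetic samples, (MR) their union; always test on the
held-out last 20% of real samples. The first-80/last-20 split is
deterministic by default (a seeded shuffle is available); `MR - RR` is
the "promotion". For multi-class subsets every subset of each size is
evaluated and averaged (`subsetMode = "first"` uses the first k labels
instead).

**Cross-validation analysis** (`crossValidationReport()`): stratified
10-fold cross-validation (per-class seeded shuffle, round-robin fold
assignment, so fold proportions deviate by at most one sample) over six
conditions: R, F, R-E, F-E, FR (R and F pooled), FR-E. Per-condition
mean and standard deviation are reported, and every split manifest is
kept so any accuracy can be replayed bit-exactly.

The pipeline logs (as warnings, never failures) two qualitative
orderings that usually hold once the GAN has converged: synthetic data
cross-validates at least as well as real data (synthetic samples are
more stereotyped, i.e. larger inter-class distance), and equalized
conditions match or beat raw ones. Both are stochastic claims about
tendencies, not invariants.

## Pipeline, scales and reproducibility

`runAll()` chains simulate → preprocess → train → generate → evaluate;
every artifact directory gets a `manifest.json` with the config echo,
seed and content hashes, so a rerun with the same seed can be verified
byte for byte. Defaults are the reduced desk scale: 2 classes, 100
windows per class, 120 epochs with the last 100 snapshots kept. Full
scale (1000 epochs, snapshots 901–1000, five-class subsets) is reached
by overriding `epochs`/`snapshotCount`/`nClasses`. The acceptance
script runs 2 classes x 60 windows at 60 epochs (last 50 snapshots) and
10-fold evaluation; the test suite uses the same machinery down to
40-image single-class smoke runs. These sizes are the package's chosen
desk scale; they keep a complete run in CPU minutes while exercising
every stage at full image resolution.

Real recordings enter through the same 4,097-column CSV layout the
simulator writes (`--real-data` in the CLI; one row per window, 4,096
channel-major values plus label), so the fixture path and the real-data
path share all code after ingestion.

## Known limitations

* Per-image normalization discards absolute amplitude; gestures that
  differ mainly in overall intensity are made harder to tell apart.
  This is inherent to the image encoding, not to the implementation.
* At desk scale the generator reliably learns first-order structure
  (mean image, coarse layout) but underfits fine texture; the
  acceptance checks therefore bound first-moment error rather than
  distributional distance.
* The discriminator's stated tanh/no-LeakyReLU design is kept
  faithfully; it trains more slowly than the conventional stack. The
  `leakyRelu` switch exists precisely to quantify that gap.
* Accuracies obtained on the synthetic fixture say nothing quantitative
  about real sEMG; they calibrate the harness.
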