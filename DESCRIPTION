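Package: emgGAN
Title: DCGAN-Based Data Enhancement for Multi-Channel Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts multi-channel surface electromyography (sEMG) windows
    into 64x64 grayscale images, trains a per-gesture deep convolutional
    generative adversarial network (DCGAN) to synthesize new samples,
    enhances images by discrete histogram equalization, and quantifies
    synthetic-data quality through similarity analysis (train on real,
    synthetic or mixed data; test on held-out real data) and stratified
    10-fold cross-validation over real, synthetic, equalized and mixed
    dataset conditions with default-parameter SVM and random-forest
    baselines. Includes a class-structured synthetic sEMG simulator so the
    whole pipeline runs without external recordings, and a command-line
    pipeline runner.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    signal,
    png,
    e1071,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    foreign,
    optparse
Encoding: UTF-8
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'preprocess.R'
    'image-enhance.R'
    'nn.R'
    'dcgan.R'
    'emgGAN-package.R'
    'evaluation.R'
    'gan-theory.R'
    'synthetic-emg.R'
    'pipeline.R'
LinkingTo: Rcpp
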