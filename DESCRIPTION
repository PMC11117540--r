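Package: frfteeg
Title: Fractional Fourier Graphical Analysis of EEG for Alcoholism Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A signal-processing and classification toolkit for detecting
    alcoholism from electroencephalogram (EEG) recordings. Provides
    multiscale principal component analysis (MSPCA) denoising built on a
    five-level Symlet-4 wavelet decomposition, a stage-filtered fast
    fractional Fourier transform (FrFT) that maps each EEG epoch to an
    ordered complex coefficient scatter, thirty-four geometric features of
    that scatter (circle, triangle and circumcircle areas, diagonal-line
    dispersions, octagon hull area, Poincare-style descriptors and central
    tendency measures), an ensemble feature selector combining information
    gain, ReliefF, variance, neighbourhood component analysis and
    correlation scores, six compact neural-network classifiers, and
    stratified cross-validation with confusion-matrix metrics and
    Kruskal-Wallis feature screening. A seeded synthetic EEG generator
    makes the whole pipeline runnable end to end without any external
    dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'frfteeg-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'synthetic.R'
    'classifiers.R'
    'data_io.R'
    'selection.R'
    'evaluation.R'
    'features.R'
    'frft.R'
    'wavelet.R'
    'mspca.R'
    'pipeline.R'
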