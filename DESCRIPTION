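Package: sparsepli
Title: Sparse Detection and Removal of Powerline Interference in EEG Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Suppresses narrow-band powerline interference (PLI) in
    single-channel biomedical recordings such as EEG without the spectral
    distortion of conventional notch filters. A redundant Fourier tight-frame
    dictionary (K = M*N equally spaced sinusoidal atoms, applied and adjoined
    by zero-padded FFTs) represents the digitized signal sparsely via
    basis-pursuit denoising, solved with a split augmented Lagrangian
    shrinkage (SALSA) iteration with complex soft thresholding. Spectral
    lines dominating the sparse spectrum inside the powerline band are
    selected, synthesized into a compensation waveform, and subtracted,
    leaving off-band spectral features essentially untouched. Includes a
    synthetic-signal generator, plain-text/CSV signal I/O in the style of the
    Bonn epileptology EEG files, a config-driven pipeline, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'detector.R'
    'fourier.R'
    'io.R'
    'salsa.R'
    'synth.R'
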