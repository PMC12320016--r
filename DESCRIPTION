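Package: statefeats
Title: Time-Series Feature Sets for Brain-State Classification in M/EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extraction of rich per-epoch time-series descriptor sets from
    epoched electrophysiological (MEG/EEG) recordings, and evaluation of
    their informativeness for discriminating brain states. Implements the
    41-feature 'TimeFeats' set (canonical catch22 descriptors, moments,
    Hjorth parameters, Hurst exponent, entropies, fractal and complexity
    measures, and peak-excluded aperiodic 1/f slope and offset), two
    spectral benchmark sets (mean band power in six canonical bands, and
    the full 1-100 Hz FFT spectrum), SVM classification of brain states
    under within-, between- and across-subject cross-validation schemes
    with leakage-free preprocessing and balanced accuracy, and
    correlation-distance hierarchical clustering of features. A synthetic
    multi-subject, multi-state cohort generator with oscillatory,
    aperiodic, drift and noise components makes the whole pipeline
    testable without any recording.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
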