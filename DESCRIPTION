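Package: complexhrv
Title: Complexity Measures for Heart Rate Variability and Paced Breathing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fractal-dimension, heart-rate-asymmetry and permutation-entropy
    estimators for physiological interval and waveform series (RR intervals,
    respiration, electrodermal activity), together with the preprocessing
    operators they need (detrending, shape-preserving resampling of the
    tachogram, segmentation, coloured-noise addition, binarisation), a
    frequency-domain resonance-breathing assessment scorecard with automatic
    resonance-breathing-rate selection, parameter-tuning strategies, a
    nonparametric repeated-measures statistics pipeline (Friedman, Kendall's W,
    Conover post-hoc, consistency ICC), and synthetic-data generators (fBm,
    Weierstrass graphs, a paced-breathing cohort with respiratory sinus
    arrhythmia) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
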