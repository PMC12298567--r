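Package: swayclass
Title: Postural Sway Classification from Trunk Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying postural sway behaviours from a chest-worn
    triaxial accelerometer. Reconstructs antero-posterior and medio-lateral
    displacement stabilograms from acceleration via a quasi-static gravity
    projection, extracts four sway features (maximum displacement ranges, the
    95% confidence-ellipse area and the root-mean-square path displacement)
    over sliding windows, and classifies windows into four postural classes
    (stable standing, antero-posterior instability, medio-lateral instability,
    general instability) with a small multi-layer perceptron and with a
    threshold-rule baseline whose cutoffs are set by ROC/Youden analysis.
    Includes a reliability index based on the softmax probability margin, a
    Gaussian noise-injection robustness protocol over a grid of noise levels,
    feature subsets and training regimes, and a synthetic rigid-rig signal
    generator that emulates the four motion classes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
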