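Package: lemonGrader
Title: Artificial-Vision Grading of Persian Lemons with a Simulated Sorter
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end simulation of a low-cost artificial-vision system for
    grading Persian lemons into export categories (extra, I, II). Provides a
    calibrated synthetic-lemon generator (feature vectors and rendered RGB
    images), colour-feature extraction (ROI crop, per-channel histograms and
    peaks, colour intensity, HSV), a shallow 7-5-3 sigmoid/softmax neural
    classifier trained by scaled conjugate gradient on cross-entropy, and a
    physics simulation of a three-phase variable-reluctance stepper-motor
    sorter gated by the classifier's output probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    png,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
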