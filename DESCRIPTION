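Package: oimotion
Title: Orientation-Invariant Transformations for Wearable Motion Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Makes window-based human-activity recognition from body-worn
    inertial and magnetic sensor units invariant to how each unit is
    oriented at its mounting position. Implements two transformations of
    tri-axial time series: a nine-channel heuristic transform built from
    norms of the signal and of its first- and second-order differences,
    angles between successive samples, and angles between successive
    rotation axes; and a singular-value-decomposition transform that
    re-expresses each windowed segment in its data-driven principal axes.
    Also provides the surrounding evaluation pipeline: a seeded generator
    of labelled multi-subject recordings, random per-segment rotation
    simulation, window segmentation, statistical and spectral feature
    extraction, per-subject normalization, PCA reduction, four classifiers
    (Gaussian maximum a posteriori, k-nearest-neighbor, RBF support vector
    machines, and a single-hidden-layer perceptron), and P-fold and
    leave-one-subject-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
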