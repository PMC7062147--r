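Package: emglrcn
Title: Lower-Limb Movement Classification and Knee Joint Angle Prediction
    from Surface EMG with a Transfer-Learning LRCN
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end pipeline for simultaneous recognition of lower-limb
    movements (walking, sitting with knee extension, standing with knee
    flexion) and regression of the knee joint angle from raw four-channel
    surface electromyography (sEMG) windows. Implements a long-term
    recurrent convolutional network (LRCN) with a shared convolutional
    feature extractor, an LSTM joint-angle head trained first, and a softmax
    classification head fitted afterwards by transfer learning on the frozen
    extractor; white-Gaussian-noise data augmentation at a fixed
    signal-to-noise ratio; sliding-window segmentation; k-fold evaluation
    with confusion matrices, precision/recall/F1 and normalized mean
    absolute error; and an empirical iterative algorithm (EIA) that smooths
    predicted angle traces by cubic-spline interpolation through midpoints
    of consecutive local extrema. Includes a seedable synthetic sEMG/angle
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
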