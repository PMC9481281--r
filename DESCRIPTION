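Package: ecgaae
Title: One-Class Abnormal-Heartbeat Detection with an Adversarial
    Autoencoder of Temporal Convolutional Blocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects abnormal single-lead ECG heartbeats as outliers under a
    model trained only on normal beats. Provides a synthetic ECG generator
    (Gaussian-wave P-QRS-T morphologies for normal, atrial premature, bundle
    branch block and ventricular premature beats), preprocessing (windowed-sinc
    resampling, multilevel wavelet denoising with baseline removal, R-peak
    beat segmentation into 250-sample windows, per-beat min-max normalization),
    an adversarial autoencoder built from dilated causal temporal convolutional
    residual blocks with full forward/backward passes and Adam training, an
    anomaly score combining reconstruction error and discriminator output with
    a mean-plus-one-standard-deviation threshold, and rank-based evaluation
    (accuracy, precision, recall, F1, AUC). Includes delimited-text and
    WFDB-subset input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
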