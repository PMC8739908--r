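Package: termaecg
Title: TERMA and Fractional Fourier Transform Tools for ECG Delineation
    and Arrhythmia Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Single-lead electrocardiogram (ECG) analysis built around
    two-event-related moving averages (TERMA) fused with a discrete
    fractional Fourier transform (FrFT) enhancement step.  Provides
    wavelet-based baseline-wander removal, zero-phase bandpass
    filtering, resampling and beat segmentation, FrFT peak enhancement,
    blocks-of-interest detection of R, P and T peaks, autoregressive
    beat features with knee-point order selection, supervised
    heartbeat classification (SVM with radial kernel, discriminant
    analysis, k-nearest neighbours, multilayer perceptron), detection
    and classification metrics, a synthetic-ECG generator with exact
    ground truth, and minimal WFDB/CSV readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    MASS,
    class,
    nnet,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
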