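Package: anesdepth
Title: Depth-of-Anaesthesia Classification from Single-Channel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Patient-specific classification of four depth-of-anaesthesia
    states from single-channel frontal EEG sampled at 128 Hz, using a
    bispectral-index-like trace as ground truth. Implements four signal
    processing routes feeding a pooled-covariance linear discriminant
    classifier with 10-fold cross-validation: the raw windowed signal,
    noise-assisted multivariate empirical mode decomposition (NA-MEMD),
    an amplitude-threshold linear series decomposition learner (LSDL),
    and a two-layer Gabor wavelet scattering transform. Ships a
    synthetic sedation-session generator (band-limited noise per state,
    burst suppression for the deepest state) so the full pipeline is
    testable without clinical recordings, plus a handcrafted feature set
    (time-domain, cepstral and spectral, sample entropy, Higuchi fractal
    dimension, detrended fluctuation analysis) and a benchmark harness
    reporting per-route accuracy, ranking and computational metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
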