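Package: mwdetect
Title: EEG Complexity Features and Leakage-Safe Classification of Mind Wandering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting probe-caught mind wandering from multichannel
    EEG. Implements multiscale sample, permutation and dispersion entropy,
    Higuchi and Katz fractal dimensions, detrended fluctuation analysis and
    discrete-wavelet band power as per-channel features of fixed pre-probe
    windows; probe-grouped repeated stratified cross-validation with
    class-dependent window augmentation, SMOTE balancing and minimum-redundancy
    maximum-relevance feature selection; random-forest evaluation by AUC with
    per-channel importance maps and prediction mutual information. A synthetic
    EEG cohort generator with probe schedules and ground-truth attentional
    state supports end-to-end testing without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
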