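Package: arousalpha
Title: Decoding Continuous Emotional Arousal from Alpha-Band EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links continuous subjective emotional-arousal ratings to
    parieto-occipital alpha-band EEG power. Provides a ground-truth-known
    generator of multichannel EEG with arousal-coupled narrowband alpha
    sources over 1/f backgrounds, deterministic preprocessing (cropping,
    rating resampling, epoch screening, tertile labelling), Welch spectra
    with an aperiodic 1/f fit and individual alpha-peak detection,
    spatio-spectral decomposition (SSD) with spectral component selection,
    source power comodulation (SPoC) with phase-randomized surrogate
    permutation tests, common spatial patterns (CSP) decoding with
    analytic-shrinkage LDA, randomized and sub-blocked cross-validation,
    SMOTE balancing and block-permutation nulls, a small LSTM sequence
    classifier, and subject- and group-level statistical evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
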