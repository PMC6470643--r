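Package: eegfusion
Title: Hybrid Spectral and Complexity EEG Feature Fusion for Brain-State
    Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discriminating clinical brain states (coma-like versus
    brain-death-like) from multichannel EEG. Implements parametric power
    spectral density estimation by the Yule-Walker autoregressive method with
    sliding Hamming windows, relative band power over the canonical EEG
    sub-bands (delta to gamma2), permutation entropy and its time-varying
    form, a multitaper time-varying spectrum built on AR estimates, PCA
    reduction with an explained-variance rule, SVD-based canonical
    correlation feature fusion, one-way ANOVA with Bonferroni correction,
    and a Gaussian-kernel SVM evaluated by leave-one-out cross-validation
    with a nested coarse-to-fine grid search. A synthetic two-class EEG
    cohort generator with controllable band-power profiles and pattern
    diversity makes the full pipeline testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    quadprog,
    Matrix,
    RSpectra
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
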