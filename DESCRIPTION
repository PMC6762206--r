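Package: ecogcv
Title: Syllable Decoding, Channel Capacity, and Cross-Frequency Coupling
    for Speech ECoG
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for electrocorticographic (ECoG) recordings
    from ventral sensorimotor cortex during consonant-vowel syllable
    production. Provides a Gaussian filterbank analytic-amplitude feature
    extractor with baseline z-scoring and constant-ratio downsampling,
    softmax classifiers (multinomial logistic regression and fully connected
    networks) under stratified cross-validation with random hyperparameter
    search, information-theoretic evaluation of classifier confusions
    (mutual information, exact channel capacity by alternating maximization,
    the uniform-error capacity approximation, and information transfer
    rate), hierarchical clustering of soft confusion matrices against
    articulatory feature spaces, and disaggregated beta-to-high-gamma
    amplitude-amplitude coupling analysis with an activity-threshold fit.
    A seeded synthetic-data generator with articulator-structured spatial
    activity and planted cross-frequency coupling makes every stage testable
    without access to human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    mclust,
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
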