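Package: eegvalence
Title: EEG Feature Extraction, Electrode Selection and Classification for
    Valence Emotion Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing electroencephalography (EEG) features in
    valence emotion recognition. Extracts time-domain (standard deviation,
    first/second-order differences, Higuchi fractal dimension, approximate
    and sample entropy), frequency-domain (Welch band power spectral
    density), time-frequency (short-time-Fourier band power and
    differential entropy), brain-network (Pearson, coherence and
    phase-locking-value connectivity with weighted clustering coefficient,
    characteristic path length, local and global efficiency) and spatial
    asymmetry (differential and rational asymmetry) features from
    multichannel epoched EEG; ranks features per subject with
    minimum-redundancy maximum-relevance (mRMR) selection and counts
    important electrodes across subjects; and runs the cross-validated
    classification protocols used to compare features (one-versus-rest
    balanced resampling, five-class stratified cross-validation, and
    rating-windowed high/low-valence sample construction) with six shallow
    classifiers. Includes a seeded synthetic-EEG generator (1/f background,
    band-limited oscillators, class-dependent spectral effects) that
    provides a ground-truth test bed, plus EDF and binary-container I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    randomForest,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
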