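Package: nirha
Title: Chemometrics and Machine Learning for Near-Infrared Classification
    of Low-Molecular-Weight Hyaluronic Acid Solutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating acid-degraded from enzyme-hydrolyzed
    low-molecular-weight hyaluronic acid (LMWHA) in aqueous solution from
    near-infrared absorbance spectra. Provides a seeded two-class synthetic
    spectrum generator, Savitzky-Golay smoothing, multiplicative scatter
    correction and global min-max normalization, generalized two-dimensional
    correlation spectroscopy (synchronous/asynchronous maps with Noda
    sequential-order rules), aquaphotomics aquagrams over the twelve water
    matrix coordinates, PCA/kernel-PCA/t-SNE embeddings, classical classifiers
    (PLS-DA with leave-one-out cross-validation, RBF and nu support vector
    classification with grid-search, genetic-algorithm and particle-swarm
    hyperparameter optimization, random forests with out-of-bag diagnostics
    and importances), native seven-layer 1D convolutional and LSTM neural
    classifiers, and confusion-matrix/ROC evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    mixOmics,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
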