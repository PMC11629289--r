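Package: trfliver
Title: Time-Resolved Fluorescence Simulation, Decay Fitting and Tissue
    Classification for Optical Liver Biopsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for time-correlated single-photon counting (TCSPC)
    fluorescence-lifetime analysis of liver tissue. Simulates photon-counting
    fluorescence decay histograms for four tissue classes (liver parenchyma,
    benign tumor, hepatocellular carcinoma, metastases) with Poisson counting
    noise and a configurable Gaussian instrument response function; fits the
    bi-exponential NAD(P)H decay model by weighted nonlinear least squares
    with reduced chi-square diagnostics; applies variance and
    pairwise-correlation feature filters with a PCA explained-variance audit;
    and trains and evaluates LDA, random-forest, polynomial-kernel SVC and
    logistic-regression classifiers under a repeated stratified 80/20 split
    protocol with sensitivity, specificity, accuracy, F1 and ROC-AUC
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    MASS,
    randomForest,
    e1071,
    nnet,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
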