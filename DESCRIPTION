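Package: solupred
Title: Protein Solubility Prediction from Sequence-Derived Features with
    an LSTM Ensemble
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Escherichia coli protein solubility from amino-acid
    sequence. Encodes sequences with five physicochemical descriptor
    families (amino-acid composition, dipeptide composition, CTD
    composition, amphiphilic pseudo-amino-acid composition and
    quasi-sequence-order), 19 global physicochemical features, and a
    skip-gram k-mer embedding; selects an informative descriptor subset
    with a genetic algorithm; and classifies with a soft-voting ensemble
    of ten LSTM networks trained on stratified folds. Includes a
    synthetic-data generator with controllable compositional solubility
    signal, binary-classifier evaluation metrics (accuracy, sensitivity,
    specificity, Matthews correlation, ROC/AUC), and a command-line
    interface for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    MASS,
    Matrix,
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
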