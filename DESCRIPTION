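Package: protint
Title: Protein-Centric Protein-Protein Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting the interaction partners of a single
    target protein from primary sequence. Given a list of known partners and
    a background proteome, it removes redundant sequences by global-alignment
    identity, samples homology-filtered negative examples, encodes proteins
    as amino-acid composition plus binary functional-domain indicators, ranks
    features by F-score, trains a radial-basis-function support vector
    machine with grid-searched hyperparameters under stratified cross
    validation, calibrates class probabilities, and scans a whole proteome
    for new candidate partners. Includes a synthetic proteome generator with
    planted compositional and domain signal for calibration and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    e1071,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
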