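Package: thermoSCM
Title: Scoring Card Method for Predicting and Characterizing Thermophilic
    Proteins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the scoring card method (SCM) for sequence-based
    prediction of thermophilic proteins. Protein sequences are encoded as
    g-gap dipeptide compositions (400 ordered residue pairs separated by g
    intervening residues); a propensity score in [0, 1000] is estimated for
    every dipeptide from class-mean composition differences and refined with
    a real-valued genetic algorithm whose fitness combines cross-validated
    AUC with correlation to the initial scores. A protein is classified by
    comparing its composition-weighted propensity sum against a learned
    threshold. The package also derives per-residue propensities, correlates
    them with AAindex physicochemical scales for interpretation, provides
    confusion-matrix metrics, ROC/AUC and stratified cross-validation, and
    includes a two-class Markov-chain sequence simulator with planted
    dipeptide biases for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
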