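Package: rawalk
Title: Random-Walk-on-Graph Classification for Protein Subcellular Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lazy multi-step random-walk classifier on RBF similarity graphs
    for predicting protein (sub)cellular localization, together with the
    supporting protein descriptors and evaluation harness. Proteins are encoded
    as 20 position-specific scoring matrix (PSSM) column means concatenated
    with a pseudo-amino-acid composition (PseAA), giving 40 + lambda features.
    The classifier builds a complete similarity graph over labeled feature
    vectors, weights the two halves of a complementary stratified split by
    their cross-prediction losses, and scores test points through a
    regularized kernel projection of the t-step lazy walk operator. Includes
    readers for FASTA and PSI-BLAST ASCII PSSM files, stratified k-fold
    cross-validation with per-class sensitivity/precision/specificity and
    one-vs-rest ROC/AUC, parameter sweeps over laziness and walk length, a
    gamma grid search, synthetic data generators, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
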