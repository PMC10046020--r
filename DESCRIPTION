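Package: cpprop
Title: Cell-Penetrating Peptide Propensity Prediction and Sequence Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the cell-penetrating propensity of peptides and proteins
    from sequence alone. Peptides are decomposed into overlapping 9-residue
    windows, an ensemble of five small neural sequence classifiers (embedding,
    convolution, LSTM and additive-attention layers, trained with Adam on
    binary cross-entropy) scores each window, and window scores are aggregated
    into peptide scores, per-residue propensity profiles and whole-protein
    scans. Proteome-derived 9-mers can be added as negatives to curb false
    positives. A sequence-space optimizer exhaustively enumerates and scores
    all variants of a wild-type peptide within a substitution budget and
    summarizes surviving variants as position frequency matrices. Includes a
    seeded synthetic-data generator, the usual binary-classification metrics
    (AUC, ACC, SEN, SPE, PRE, MCC), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
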