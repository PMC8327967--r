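Package: casid
Title: Identification of Cas Proteins from Dipeptide Composition with
    Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies CRISPR-associated (Cas) proteins from amino-acid
    sequence. Protein sequences are encoded as 400-dimensional dipeptide
    composition vectors, features are ranked by an F-score filter statistic
    (or random-forest mean-decrease impurity) and selected by incremental
    search with inner five-fold cross-validation, and classification uses a
    radial-basis-function support vector machine with grid-searched
    hyperparameters and probability output. Includes leakage-free nested
    cross-validation protocols, classification metrics (sensitivity,
    specificity, accuracy, Matthews correlation coefficient, ROC/AUC), a
    chi-square comparison of positive-call rates, a deterministic synthetic
    sequence generator for benchmarking, and an optional profile-HMM
    annotation stage wrapping HMMER3 to assign Cas family labels to
    predicted Cas proteins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
SystemRequirements: HMMER3 (hmmbuild, hmmpress, hmmscan) for the optional
    profile-HMM annotation stage
Config/testthat/edition: 3
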