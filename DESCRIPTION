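Package: promethyl
Title: Promoter 5-Methylcytosine Site Prediction with a Down-Sampling
    Ensemble of Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts 5-methylcytosine (5mC) modification sites in promoter
    DNA sequences. Candidate cytosines are represented as fixed-length
    windows (strand-aware, reverse-complemented for the minus strand),
    encoded by one-hot vectors, deoxynucleotide chemical properties plus
    cumulative base frequency (DPF), or their fusion, and classified by an
    ensemble of shallow fully connected neural networks. Class imbalance is
    handled by partitioning the negatives into equal groups, training one
    balanced sub-model per group, and fusing sub-model decisions by strict
    unanimity. Includes stratified cross-validation, sensitivity,
    specificity, accuracy, Matthews correlation and ROC/AUC metrics, a
    seeded synthetic-data generator with a tunable planted CpG-flavoured
    motif, FASTA scanning with BED output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
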