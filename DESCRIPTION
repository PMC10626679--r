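Package: kmst
Title: Reference-Free Microbial Source Tracking with Binary k-mer Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the contribution of labelled source environments
    (such as ancient oral, modern oral, skin, and sediment/soil
    metagenomes) to a metagenomic sink sample, using presence/absence
    matrices of canonical k-mers instead of taxonomic profiles. Sources
    are encoded as a binary k-mer-by-sample matrix with one-hot
    environment labels; each k-mer shared between the sink and a source
    adds one "ball" to that source's environment bin, and the bin counts
    are normalized to proportions that sum to 100 percent. Includes a
    hard-label classifier with an explicit tie rule, an unknown-source
    fraction, leave-one-out and group-stratified cross-validation
    harnesses with macro-averaged metrics and ROC/PR curves, and a
    synthetic metagenome generator with known mixing weights so the whole
    pipeline is testable without downloading any sequencing accession.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
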