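Package: sterilamp
Title: Rapid Sterility Assessment of Cell-Therapy Cultures from Nanopore
    Amplicon Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a desk-scale sterility-assessment pipeline for
    cell-therapy cultures sequenced by long-read 16S / 18S-28S amplicon
    sequencing. Synthetic amplicon runs with host-read dominance, low-CFU
    contaminant tiers and kitome background are simulated; reads are
    assigned to taxa with a canonical k-mer classifier (or by parsing
    Centrifuge and BLAST outfmt-6 tables); host reads are depleted by
    read-ID subtraction; per-species feature tables are built from read
    quality, read length and inter-read timing; two gradient-boosted
    binary classifiers (sample contaminated, contaminant correctly
    classified) are trained with a two-layer grouped split, data
    augmentation, correlation-aware feature selection, standard scaling
    and cross-validated grid search; and a configurable decision matrix
    combines the two models into a four-state sterility call per sample.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    Rcpp,
    xgboost,
    jsonlite,
    rpart,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
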