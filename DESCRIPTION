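Package: cloneBarcodes
Title: Selection of Informative Amplicon Barcodes for Clonal Lineage Tracing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies clonal diversity from CRISPR amplicon barcodes
    (GESTALT-style tandem target arrays) sequenced across experimental
    replicates. Provides bespoke paired-end read merging, sliding-window
    quality trimming and primer filtering, global affine-gap alignment with
    CIGAR-based indel variant naming, a cross-sample Sharing Factor statistic
    with threshold-sweep selection of the common-variant cutoff, BCa
    bootstrap selection of informative samples, clone enumeration with
    Shannon and inverse Simpson diversity, longitudinal sample matching, and
    a synthetic-data generator with complete truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    boot,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
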