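Package: pseudosplice
Title: Characterisation of Pseudoexon-Activating Deep-Intronic Variants and
    Antisense Blocker Design
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising deep-intronic single-nucleotide variants
    that activate pseudoexons (cryptic exons) in a gene locus, and for
    designing antisense molecules (modified U7 snRNA and circular RNA
    carriers) that block them. Provides a candidate-variant filter cascade
    driven by SpliceAI delta scores, position-weight-matrix and
    maximum-entropy splice-site strength scoring, exonic-splicing-enhancer
    motif scanning, background-splicing event calling from splice-junction
    tables, pseudoexon grouping and naming, frame/PTC consequence annotation,
    fragment-analysis isoform quantification, an ensemble-based RNA
    accessibility model for antisense target ranking, and a seeded stochastic
    minigene-splicing simulator so that the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: AlternativeSplicing, Transcriptomics, Software, SNP
Config/testthat/edition: 3
RoxygenNote: 7.3.3
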