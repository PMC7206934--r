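Package: cpedit
Title: Chloroplast C-to-U RNA Editing Detection and Comparative Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to call C-to-U RNA editing sites in chloroplast genes by
    global alignment of transcript (cDNA) sequences against genomic coding
    sequences, annotate codon-level consequences and amino-acid property
    changes, profile the sequence context flanking edited cytidines, compare
    editing sites across species, rank loci by
    parsimony-informative-character content for phylogenetic supermatrix
    export, and screen hydropathy profiles for transmembrane-segment changes
    between edited and unedited protein forms. A synthetic-data generator
    with a ground-truth ledger supports end-to-end validation of every
    stage without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    generics,
    ape,
    Biostrings,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
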