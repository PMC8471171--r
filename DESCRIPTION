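Package: promethex
Title: Promoter Hypermethylation with Transcriptional Activation: Integration, TF Screening and Validation Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for identifying genes whose promoter
    hypermethylation coincides with transcriptional up-regulation, and for
    characterising the transcription factors that read methylated DNA.
    Provides differential promoter methylation and differential expression
    with empirical-Bayes moderated t-statistics and Benjamini-Hochberg
    control; quadrant classification of joint methylation-expression
    changes; scoring of protein-microarray incubations with methylated
    versus unmethylated DNA fragments; methylation-aware position weight
    matrix scanning over an extended {A,C,G,T,M} alphabet with exact
    p-values; Fisher's-exact overrepresentation and gene set enrichment
    analysis; and quantification of validation assays (bisulfite clone
    methylation, delta-delta-Ct qPCR, ChIP percent-input, dual luciferase).
    A synthetic-data generator with planted ground truth drives end-to-end
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    Biostrings,
    S4Vectors,
    GenomicRanges,
    IRanges,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
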