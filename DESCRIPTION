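Package: mirvar
Title: Discovery of miRNA Precursors and Mutation/Editing Sites from
    Small RNA Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for the analysis of small RNA
    sequencing profiles: preprocessing (quality gating, 3' adapter
    trimming, read collapsing), discovery of conserved and
    species-specific miRNA precursors via native hairpin folding and
    structural criteria, alignment of collapsed reads to precursors
    with non-templated 3' tail handling, cross-mapping correction of
    multi-mapped reads, identification and classification of
    mutation/editing (M/E) sites with exact binomial significance
    testing and multiple-testing correction, SNP calling against a
    variant table, cross-species matching of conserved editing sites,
    miRNA expression quantification (RPTM), seed-match target
    prediction for original versus edited miRNAs, and generic
    hypergeometric set enrichment. Includes a synthetic small RNA-seq
    data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
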