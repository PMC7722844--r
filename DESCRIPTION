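Package: silentscan
Title: Transgene-Silencing Genomics Toolkit for Multi-Strain Chlamydomonas Surveys
Version: 0.9.0
Authors@R:
    person("silentscan", "developers", email = "silentscan@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-strain studies of epigenetic
    transgene silencing in Chlamydomonas reinhardtii. Implements a
    transposon-mobility survey based on half-mapped paired-end reads
    (TE-anchored mate classification, anchor re-mapping, coverage-interval
    locus calling, multi-strain presence/absence scoring and differential
    flagging), cross-strain variant triage with CAPS restriction-marker
    design, differential-expression statistics (FPKM, Benjamini-Hochberg
    adjustment, directional Venn candidate sets), ChIP-qPCR percent-input
    normalization, genetic-mapping and complementation (YET) scoring, and
    neighbor-joining phylogenetics with Poisson-corrected protein distances
    and bootstrap supports. Ships seeded synthetic-data generators (strain
    genomes with planted insertions, paired-end reads, negative-binomial
    count matrices, Cq tables, segregant genotypes, annotated variants) and
    a built-in seed-and-extend read mapper so the whole pipeline runs
    end-to-end without external aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
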