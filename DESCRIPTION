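Package: cageshift
Title: CAGE Promoter Usage, Promoter Shifting, and Allelic Imbalance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of promoter architecture from Cap Analysis of Gene
    Expression (CAGE) data in two-strain rodent designs: extraction of
    CAGE-defined transcription start sites (CTSS) from alignments,
    single-linkage tag clustering and tags-per-million normalisation,
    promoter grouping, gene assignment and expression ranking, CpG/TATA
    architecture classification, negative-binomial differential promoter
    expression with alternative-promoter-usage calling, count-weighted
    Kolmogorov-Smirnov detection of within-promoter TSS shifts, exact
    binomial allelic-imbalance testing in F1 hybrids, recombinant-inbred
    genotype-phenotype association, pseudo-genome construction by SNV
    substitution, and a fully self-contained synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
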