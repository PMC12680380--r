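Package: zoymap
Title: Linkage Mapping and Binary-Trait QTL Analysis for Interspecific F2
    Crosses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building high-density genetic linkage maps and mapping
    binary-trait quantitative trait loci (QTL) in F2 intercross populations
    genotyped by sequencing, with emphasis on interspecific crosses such as
    Zoysia japonica x Zoysia matrella. Variant calls are converted to mapping
    scores with ambiguous partial codes (C = "B or H", D = "A or H"),
    phase-unknown markers are resolved by duplication and score reversal,
    linkage groups are assembled by two-point likelihood at a LOD threshold,
    markers are ordered by seriation with 2-opt polishing, and map distances
    use the Kosambi function. QTL scanning uses conditional genotype
    probabilities from a hidden Markov model and Haley-Knott regression with
    permutation-based genome-wide thresholds. A two-site intragenic model of
    tissue-specific anthocyanin loss, in-silico CAPS genotyping, a synthetic
    F2/F1 cross simulator with transmission-ratio distortion, and map summary
    reports are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
biocViews: Genetics, GeneticVariability, LinkageDisequilibrium, SNP,
    Software
RoxygenNote: 7.3.3
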