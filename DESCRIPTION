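Package: cnvpop
Title: Population Genomics of Copy-Number Variation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for population-level analysis of copy-number
    variants (CNVs) in resequenced cohorts. Integrates per-individual
    calls from multiple structural-variant callers into a filtered
    consensus and cross-individual CNV regions, genotypes loci from
    normalized read depth, classifies bi-allelic deletion and
    duplication loci and builds allele-frequency spectra, computes the
    signed V_ST copy-number differentiation statistic between
    population pairs, classifies geographic sharing of variants along a
    population/country/continent hierarchy, detects homozygous gene
    losses, estimates the scaled selection coefficient gamma from the
    site-frequency spectrum under a Poisson Random Field model, and
    tests gene-category enrichment among CNVs with length- and
    chromosome-matched permutations. A synthetic-cohort simulator
    generates all pipeline inputs with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
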