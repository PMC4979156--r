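Package: tenet
Title: Transposable Element Neighborhoods and Histone Modification Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Gene-centric analysis of the transposable element (TE) environment
    of genes and its association with histone modification changes between two
    cellular conditions. Computes per-gene TE density and coverage over the
    gene body plus flanking regions, mean histone enrichment from broadPeak
    ChIP-seq intervals, classifies genes into TE-content categories with a
    deterministic partitioning-around-medoids (PAM) clustering implemented
    from scratch, profiles genes along chromosomes in 5 percent bins, and
    provides the two-condition statistical layer: differential enrichment,
    rank-based tests, category contingency tables, and chi-square homogeneity
    tests with Bonferroni control. Includes a synthetic-genome generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    withr
Config/testthat/edition: 3
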