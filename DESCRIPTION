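Package: hmcdyn
Title: Locus-Specific 5mC and 5hmC Peak Dynamics in Normal Versus Cancer Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative locus-specific analysis of DNA methylation (5mC) and
    hydroxymethylation (5hmC) peak sets from affinity-enrichment sequencing of
    paired normal and cancer cell lines. Provides genomic-feature annotation of
    peaks (promoter, genic, exon, intron, intergenic, CpG island, DNase
    hypersensitive site windows), replicate consensus and presence/absence
    differential peak sets, expression-tier association statistics (chi-square
    test for trend, Pearson correlation, Fisher exact test), cross-cell-line
    classification of 5hmC fate (absence, retention, gain) tested against dual
    marginal-distribution nulls, same-cell-line 5mC/5hmC co-incidence,
    inter-technique concordance, region-based hypergeometric gene-set
    enrichment with enrichment-map edges, and delta-delta-Ct qPCR fold
    quantification. A seeded synthetic-data generator emulates the statistical
    structure of the assays so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    jsonlite,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
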