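Package: desertsweep
Title: SNP Quality Control, Population Structure, Haplotype-Based
    Selection Scans and Genome-Transcriptome Association
Version: 0.1.0
Authors@R:
    person("Desertsweep", "Developers", email = "desertsweep@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for detecting selective sweeps in livestock
    SNP-chip panels and relating them to stage-specific gene expression.
    Provides marker-level quality control (call rate, minor allele
    frequency, Hardy-Weinberg exact test), population structure tools
    (Patterson-scaled PCA, p-distance matrices, neighbor-joining trees,
    linkage-disequilibrium pruning and decay curves), from-scratch
    implementations of four complementary selection statistics (per-SNP
    Weir-Cockerham FST, iHS, xp-EHH and Rsb via extended haplotype
    homozygosity integrals), top-percentile candidate-gene calling with
    UpSet-style set intersections, and an FPKM-based least-squares
    t-statistic for stage-specific expression gene sets intersected with
    the sweep candidates. A deterministic synthetic-data module generates
    haplotypes with implanted hard sweeps, genotypes with planted QC
    violations, toy annotations and stage-structured expression with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    ape,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
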