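Package: dualqtl
Title: Classical and Modified eQTL Mapping with Somatic DNA Segment
    Alteration Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrated cis-eQTL and somatic alteration analysis for
    paired tumor/normal expression cohorts. Maps SNPs to pathway genes
    via flanking windows, screens SNPs by case-control logistic
    association, computes Spearman rank-correlation eQTL statistics in
    two modes (normal-tissue signal and tumor/normal log2 fold change),
    intersects the two scans and classifies direction-flipped SNP-probe
    pairs, calls per-gene somatic copy-number gain, loss/LOH and allelic
    imbalance from paired SNP-array logR/BAF signals, and characterizes
    shared genes by paired differential expression (BH FDR) and
    Kaplan-Meier log-rank survival splits. Ships a seeded synthetic-data
    generator emulating the full input bundle so the pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    survival,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
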