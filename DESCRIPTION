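Package: pathgwas
Title: Pathway-Based Analysis of Case-Control GWAS with GSEA and ARTP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pathway (gene-set) analysis of case-control genome-wide
    association data. Implements covariate-adjusted per-SNP logistic trend
    tests, reduction to best-SNP gene statistics, two complementary gene-set
    enrichment tests (a weighted Kolmogorov-Smirnov enrichment score and the
    adaptive rank-truncated product) sharing a single genotype-permutation
    null, permutation-normalized scores with a permutation-based false
    discovery rate, and a cross-study Cochran's Q / I-squared heterogeneity
    filter for SNPs with study-inconsistent effects. Includes a synthetic
    multi-study GWAS generator with linkage-disequilibrium blocks, gene and
    pathway annotation layouts, and configurable causal and heterogeneous
    effects for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
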