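Package: nlqtl
Title: Non-Linear Molecular QTL Mapping with Quantile Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mapping and characterization of non-linear molecular quantitative
    trait loci (QTL). Implements the quantile rank-score test with Cauchy
    combination across quantile levels (quantile QTL, qQTL), a rank-score
    contrast test for variance QTL (vQTL), linear interaction QTL (iQTL)
    mapping with directionality classification, two-stage hierarchical
    multiple-testing correction, classification of quantile versus linear
    (xQTL) discoveries including Chatterjee-correlation heterogeneity tests,
    quantile-based transcriptome-wide association (qTWAS) with LD-aware
    summary-statistic testing over fixed or data-driven quantile regions,
    excess-of-overlap enrichment with leave-one-chromosome-out jackknife
    errors, hypergeometric gene-set over-representation, a synthetic-data
    generator for all pipeline inputs, and a Monte-Carlo study comparing
    iQTL, qQTL and xQTL detection under genotype-by-factor interactions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    quantreg,
    data.table,
    igraph,
    vcfR,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
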