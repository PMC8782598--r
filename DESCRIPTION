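Package: ldnb
Title: Landscape Dynamic Network Biomarker Analysis for Time-Series Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects critical transitions (tipping points) in time-series gene
    expression data with the landscape dynamic network biomarker (l-DNB)
    framework. Builds single-sample networks (SSNs) from the change in Pearson
    correlation caused by adding one case sample to a reference cohort, scores
    each gene's local network module by combined expression deviation,
    intra-module correlation and module-outside correlation, aggregates scores
    to time points to call the tipping point, derives differential (rewiring)
    networks around it, prioritizes core biomarker genes against an anchor
    signature list over a protein-protein interaction background, and tests
    phenotype-decline risk between high- and low-expression groups with a
    fixed-group-size chi-square statistic. Includes a synthetic time-series
    generator with a planted biomarker module for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
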