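Package: chiasmetry
Title: Quantitative Analysis of Chiasma Localization and Crossover Class
    Statistics in Pollen Mother Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of meiotic
    crossover/chiasma localization from cytological observations in pollen
    mother cells. Classifies chiasma positions along bivalent arms into
    proximal, interstitial and distal regions; summarises per-sample
    chiasma frequency and regional distribution; compares distributions
    between samples with Pearson chi-square tests, Cramer's V effect sizes
    and Bonferroni-adjusted pairwise tests; computes per-cell MLH1 (class
    I crossover) and MUS81 (class II crossover) immunofluorescence focus
    statistics, including Wilcoxon rank-sum comparisons with false
    discovery rate control and a cross-product "artificial population"
    weighted-mean ratio estimator for markers scored on separate slides.
    Includes a seeded synthetic pollen-mother-cell data generator with an
    obligate-crossover constraint and Beta-distributed arm positions, and
    utilities for longest-ORF translation and pairwise amino-acid identity
    of transcript sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
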