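Package: mrwald
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: instrument assembly with LD-proxy substitution,
    allele harmonization with configurable handling of palindromic
    variants, causal-effect estimation by inverse-variance weighting,
    the weighted-median estimator and MR-Egger regression, sensitivity
    analyses (leave-one-out, gene-subset, heterogeneity), scale
    transformations to odds ratios or clinical units, and a
    summary-level simulator with known truth for calibration studies.
    Ships transcriptions of the published instrument and outcome tables
    for the serum 25-hydroxyvitamin D and dental caries analysis as
    worked-example fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
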