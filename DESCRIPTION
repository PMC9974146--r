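Package: bimr
Title: Bidirectional Two-Sample Mendelian Randomization for Microbiome-Disease Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization (MR)
    between a panel of exposures (such as gut-microbiome taxa) and a binary
    disease trait, using GWAS summary statistics. Covers instrument selection
    (significance and minor-allele-frequency filters, greedy LD clumping,
    proxy substitution, F-statistic screening), allele harmonization of
    exposure and outcome effects, the Wald ratio and five multi-instrument
    causal estimators (inverse-variance weighted, MR-Egger, weighted median,
    weighted mode, simple mode), and a sensitivity suite (Cochran's Q,
    MR-PRESSO global and outlier tests, leave-one-out analysis). A synthetic
    summary-statistics generator with known causal ground truth supports
    power studies and end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
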