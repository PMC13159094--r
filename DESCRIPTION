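Package: mrmediate
Title: Three-Step Mendelian Randomization with Metabolite Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-sample Mendelian randomization toolkit for screening many
    exposures against a disease outcome and resolving mediation through an
    intermediate trait. Provides instrument selection (p-value threshold,
    greedy LD clumping, F-statistic filter), exposure-outcome allele
    harmonization, five causal-effect estimators (inverse-variance weighted,
    MR-Egger, weighted median, simple and weighted mode), sensitivity
    diagnostics (Cochran's Q, Egger intercept, MR-PRESSO, leave-one-out),
    reverse-MR exclusion, and product-of-coefficients mediation with
    delta-method standard errors. A seeded simulator generates two-sample
    GWAS summary statistics with known causal structure so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
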