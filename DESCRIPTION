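Package: hitenrich
Title: Inference for Hit Enrichment Curves in Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and statistical inference for hit enrichment curves
    used to evaluate ligand ranking algorithms in virtual screening.
    Provides tie-safe empirical curve and enrichment-factor estimation,
    pointwise hypothesis tests and confidence intervals for the difference
    in recall between two scoring methods (an empirical-process procedure
    accounting for within- and between-algorithm correlation, plus
    independent Jiang-Zhao, correlated-binomial, and McNemar variants with
    Bonett-Price style adjustments), simultaneous sup-t, Bonferroni, and
    theta-projection confidence bands for single curves and curve
    differences, and a seeded Monte-Carlo harness (binormal, bibeta, and
    uniform score models with Gaussian-copula correlated scores) for
    type-I error, power, and coverage studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
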