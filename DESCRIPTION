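Package: mrmediate
Title: Two-Sample Mendelian Randomization and Two-Step Mediation for
    GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) and two-step
    MR mediation analysis from GWAS summary statistics. Reads and harmonizes
    summary-association tables, selects genetic instruments (genome-wide
    significance with a documented fallback threshold, greedy LD clumping,
    F-statistic filtering), and estimates causal effects with the inverse
    variance weighted, MR-Egger, weighted median, simple mode and weighted
    mode estimators plus multivariable IVW for mediator effects adjusted for
    the exposure. Provides Cochran Q heterogeneity, Egger-intercept
    pleiotropy and leave-one-out diagnostics, a delta-method decomposition
    of mediated effects with confidence intervals for the proportion
    mediated, a screening pipeline over panels of candidate mediators with a
    reverse-MR guard, and a seeded generator of GWAS summary statistics for
    exposure-mediator-outcome causal systems with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
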