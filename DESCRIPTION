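Package: mrpipe
Title: Bidirectional Two-Sample Mendelian Randomization with Instrument
    Accounting, Sensitivity Diagnostics and Two-Step Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization workflow for GWAS
    summary statistics: an instrument-selection cascade (significance screen,
    LD clumping, weak-instrument F filter, allele harmonization, confounder
    screen, MR-PRESSO outlier removal, Steiger directionality filter and
    per-SNP Bonferroni outcome filter) with stage-by-stage accounting; five
    causal-effect estimators (Wald ratio, multiplicative random-effects IVW,
    MR-Egger, weighted median, weighted mode, robust adjusted profile score);
    a sensitivity suite (Cochran's Q, Rucker's Q', Egger intercept, I2_GX /
    NOME flag, leave-one-out, MR-PRESSO global and distortion tests, Steiger
    direction, analytic power); a primary-method decision rule with
    Benjamini-Hochberg correction and power filtering; and two-step MR
    mediation with proportion mediated. Includes a seeded synthetic
    summary-statistics generator with known causal structure so the entire
    pipeline is testable without external cohort data.
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
    withr
Config/testthat/edition: 3
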