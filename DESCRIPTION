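Package: stepsig
Title: StepMiner Thresholding and Composite Gene-Signature Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Adaptive one-step regression (StepMiner) thresholding of
    per-gene expression, threshold-centered normalization, composite
    gene-signature scoring and ROC-AUC cohort classification, a
    simplified differential-expression stage with TPM summarization and
    the P <= 0.05 / fold-change >= 2 selection rule, hypergeometric
    gene-set enrichment, multivariate covariate regression, and
    Kaplan-Meier/log-rank survival stratification by a signature
    metagene. Includes a negative-binomial synthetic-cohort generator
    with planted signatures so the whole pipeline is testable without
    external data, and a subcommand command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
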