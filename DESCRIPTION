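Package: betaclock
Title: Maximum-Likelihood Epigenetic Age Prediction from Methylation Beta Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A two-stage epigenetic clock for microarray DNA-methylation beta
    values. CpG sites are ranked by Spearman correlation of methylation with
    chronological age, reference curves of expected methylation per integer age
    (0-100) are fitted with tricube local-linear (LOWESS) smoothing, and
    per-site variances are estimated from same-age samples treated as technical
    replicates. Ages are predicted by maximizing the summed per-site
    log-density (normal or beta likelihood) over the age grid. A second stage
    retrains cohort-specific references for junior and senior samples split at
    a cutoff age chosen by minimal mean bias error, and routes test samples by
    their first-stage estimate. Includes a synthetic beta-value generator,
    cross-validation and residual diagnostics, penalized-regression baselines,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
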