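Package: trueprev
Title: True Prevalence Estimation Under Diagnostic Misclassification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of true disease prevalence from apparent prevalence
    observed with an imperfect diagnostic test. Implements the Rogan-Gladen
    misclassification-adjusted point estimate with five 95% confidence
    interval constructions (Clopper-Pearson, Sterne, Blaker,
    Wald-Rogan-Gladen, Lang-Reiczigel) and a Bayesian beta-binomial
    misclassification model fitted by a data-augmented Gibbs sampler with
    Gelman-Rubin convergence diagnostics, posterior mean and highest density
    interval. Includes a full simulation-validation pipeline: random
    generation of true parameter scenarios, binomial data simulation,
    estimation for every data set, and validation by estimation-error
    distributions, per-scenario interval coverage, interval length, and
    Deming errors-in-variables regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    coda,
    yaml
Config/testthat/edition: 3
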