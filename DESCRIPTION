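Package: effortdm
Title: Effort-Based Decision-Making: Task Simulation, Hierarchical
    Bayesian Modelling, and Covariate Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an adaptive effort-expenditure task (four effort by
    four reward levels, sixteen interleaved staircases, 64-trial sessions),
    implements a nine-model family of subjective-value choice models
    (linear, parabolic, and exponential effort costs crossed with three
    parameter configurations) with hierarchical Bayesian fitting via JAGS,
    Pareto-smoothed importance-sampling leave-one-out model comparison,
    posterior predictive checks, and parameter recovery.  Downstream
    analyses link model parameters to neuropsychiatric questionnaire
    measures (partial least squares with permutation tests, Bayesian
    generalized linear models) and to circadian phenotype (chronotype
    classification, synchrony-effect models, precision-based stopping
    rule), plus test-retest reliability.  A synthetic-population generator
    provides agents and covariate tables with the generative structure the
    analyses assume, so the whole pipeline runs without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
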