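Package: limamr
Title: Likelihood-Based Mediation Analysis from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the mediation proportion (MP) of a causal effect
    between an exposure and an outcome transmitted through a set of
    molecular mediators, using only GWAS/QTL association summary
    statistics. Implements the classical two-step Mendelian randomization
    baseline (univariable IVW for the total effect, multivariable IVW for
    the direct effect), the joint maximum-likelihood estimator LiMA which
    models the sampling noise in every summary-statistic block, and the
    integrated variant I-LiMA which marginalizes individual mediator
    effects under a Gaussian prior and estimates only the direct effect
    and three prior (co)variance components. Includes a full generative
    simulator of mediation summary statistics (spike-and-slab mediation
    effects, Weibull mediator heritabilities, sample-size-scaled Gaussian
    estimation noise, optional pleiotropy variance components, IVW-based
    mediator selection), a benchmarking driver computing bias, coverage,
    power and type-I error of the mediation-proportion estimators, and a
    pipeline front end for harmonized summary-statistic tables with
    Steiger filtering, mediator selection and correlation pruning.
License: GPL (>= 3)
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
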