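Package: factorqtl
Title: Joint Bayesian Modelling of Genetic and Confounding Variation in
    Expression QTL Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps expression quantitative trait loci (eQTLs) while jointly
    accounting for known covariates, hidden confounding factors and per-gene
    noise. The core is a variational Bayesian additive model combining a
    spike-and-slab single-best-SNP genetic effect per gene, Bayesian
    regression on known covariates with automatic relevance determination
    (ARD), and a probabilistic factor analysis model of hidden confounders
    with ARD complexity control. Two inference schedules are provided: a
    joint iterative schedule that learns genetic effects together with the
    factors (retaining trans hotspot signal), and a cheaper two-stage
    schedule that learns factors first. Baseline confounder correctors
    (covariate regression, truncated PCA, permutation-calibrated PCA, and a
    surrogate-variable procedure), residual-based association tests
    (correlation t-test, rank test, permutation test, nested likelihood
    ratio), cis/trans classification, and a simulation benchmark with
    ground-truth factor and eQTL recovery metrics are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml,
    optparse,
    sva,
    withr,
    knitr
Config/testthat/edition: 3
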