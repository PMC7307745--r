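Package: cardiomap
Title: Bayesian Joint Spatial Mapping and Hotspot Detection for
    Cardiometabolic Survey Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Small-area prevalence estimation and hotspot detection for
    correlated binary cardiometabolic outcomes (diabetes, obesity,
    hypertension, high LDL cholesterol) measured in a complex health
    survey.  Fits a Bayesian hierarchical joint model with BYM-type
    spatial random effects (intrinsic CAR plus unstructured
    heterogeneity) at both the individual and the province-aggregated
    level, run in a single Metropolis-within-Gibbs chain with Bayesian
    imputation of missing outcomes and covariates.  Provides posterior
    prevalence maps, exceedance-probability hotspot flags, convergence
    diagnostics, a penalized-quasi-likelihood frequentist baseline, and
    a calibrated synthetic survey generator emulating an elongated
    chain-like geography with unequal sampling and survey weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
RoxygenNote: 7.3.3
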