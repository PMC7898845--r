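Package: ipdshrink
Title: Shrinkage Estimation of Patient-Specific Treatment Effects in
    One-Stage Individual Patient Data Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: One-stage individual patient data (IPD) meta-analysis models
    for estimating patient-specific treatment effects when many candidate
    treatment-covariate interactions are available.  Implements generalized
    linear mixed models with a random treatment effect (full and oracle
    variants), bidirectional stepwise selection of interaction terms, and
    five shrinkage estimators that penalize only the treatment-covariate
    interactions: LASSO, ridge, and adaptive LASSO (coordinate-descent and
    closed-form solvers with cross-validated penalty selection), plus two
    Bayesian models fitted by MCMC (Bayesian LASSO with a Laplace prior
    and a random treatment effect, and stochastic search variable
    selection with a spike-and-slab mixture prior).  Includes a
    multi-study data simulator with a catalog of simulation scenarios,
    mean-squared-error performance measures for patient-specific and
    average treatment effects, bootstrap standard errors, subgroup-effect
    prediction, and a replication harness for method comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    rjags,
    coda,
    jsonlite
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
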