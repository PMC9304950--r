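Package: twinwaves
Title: Longitudinal Twin Analysis of Mental-Health Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal analyses of mental-health symptoms in
    classical twin cohorts measured across repeated waves: descriptive
    change statistics (Cohen's d, repeated-measures MANOVA with partial
    eta squared, cross-wave correlations), univariate and multivariate
    ACE variance decompositions with genetic and environmental
    correlations and Cholesky innovation models fitted by
    full-information maximum likelihood, longitudinal latent profile
    analysis via constrained Gaussian mixtures, latent growth curves,
    polygenic-score association with a general psychopathology factor,
    and extreme-group trajectory contrasts. A seeded synthetic twin
    cohort generator reproduces the covariance structure every stage
    assumes, so the full pipeline runs and is testable without access
    to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
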