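Package: megprog
Title: Spectral and Riemannian MEG Biomarkers of Progression from MCI to
    AD Dementia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for magnetoencephalography
    (MEG) biomarkers of progression from mild cognitive impairment (MCI)
    to Alzheimer's disease dementia. Provides a synthetic two-site cohort
    generator with planted spectral effects, log-spaced Morlet wavelet
    spectral metrics (power, covariance, debiased weighted phase-lag
    index, power-envelope correlation), Riemannian statistics on
    symmetric positive-definite matrix sets (affine-invariant distances,
    tangent-space embedding, distance MANOVA), threshold-free cluster
    enhancement (TFCE) permutation inference across frequencies and
    sensors, additive logistic risk models with average marginal effects
    and bootstrap discrimination metrics, a cross-fitted stacked
    classifier over modality-specific ridge models, and conditional
    permutation importance with the Nadeau-Bengio corrected test.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    glmnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
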