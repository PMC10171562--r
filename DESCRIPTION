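Package: comptraj
Title: Riemannian Functional Principal Component Analysis for Sparse
    Longitudinal Compositional Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models sparsely observed longitudinal trajectories of
    three-part compositions (such as cerebrospinal fluid, grey matter and
    white matter volume fractions from pediatric neuroimaging) by mapping
    each composition to the unit sphere via the square-root transform and
    performing sparse Riemannian functional principal component analysis:
    kernel-localized Frechet mean estimation, tangent-space covariance
    smoothing, eigendecomposition, and best-linear-unbiased-prediction
    scores. Includes an energy-distance permutation test for comparing
    groups of trajectories, a random-intercept linear mixed model baseline
    with a drop-latest-scan Fisher-Rao holdout benchmark, bootstrap
    confidence regions for mean compositions on the ternary diagram, and a
    seeded synthetic-cohort generator with known Karhunen-Loeve ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    lme4,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
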