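Package: irtvalid
Title: Psychometric Validation of Polytomous Item Banks with Graded
    Response Models and Simulated Computerized Adaptive Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end validation workflow for item banks scored on ordered
    Likert categories: unidimensionality checks on the polychoric correlation
    matrix (one-factor fit indices, exploratory eigenvalue ratio), local
    dependence screening via residual correlations, non-parametric Mokken
    scaling (Loevinger H scalability coefficients and monotonicity of
    item-step response functions), logistic Graded Response Model estimation
    by marginal maximum likelihood EM, Orlando-Thissen S-X2 item fit for
    polytomous items, differential item functioning screening by ordinal
    logistic regression with the McFadden pseudo-R2 change criterion, and
    post-hoc computerized adaptive testing simulation with T-score and
    reliability reporting. A synthetic-data generator produces
    GRM-consistent respondent cohorts (including ceiling effects and
    injected DIF) so the whole pipeline is testable without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
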