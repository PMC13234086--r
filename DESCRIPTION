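Package: cotula
Title: Coupling-Tuning-Latent Models of Simultaneously Recorded Neural Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear-Gaussian models of neural population activity that combine
    functional coupling (dependence on simultaneously recorded units), tuning
    (dependence on external stimuli), and a low-dimensional latent state for
    unobserved shared variability (the CoTu and CoTuLa models), in both static
    trial-level and dynamic VAR(1) forms. Provides exact joint moments and
    likelihoods, expectation-maximization and ordinary least squares inference
    under no/oracle/inferred model-support regimes, the identifiability
    transform and a sparsity-based identifiability test, closed-form systematic
    error predictions for the univariate dynamic model, and synthetic-data
    experiment drivers that quantify and mitigate systematic estimation errors
    caused by structural non-identifiability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
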