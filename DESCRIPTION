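Package: epiconn
Title: Epigenetic Age Acceleration, Cognition, and Connectome-Based
    Predictive Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage analysis pipeline linking epigenetic age
    acceleration (AgeAccelGrim) to cognitive performance and resting-state
    functional connectivity in older adults. Provides bootstrap exploratory
    graph analysis (graphical-lasso partial-correlation networks with EBIC
    penalty selection, Louvain community detection, parametric-bootstrap item
    stability, and network community scores), a multivariate hierarchical
    robust Bayesian regression of latent cognitive scores on age acceleration
    (per-response Student-t likelihoods, correlated subject-level random
    effects, posterior tail probabilities with false-discovery-rate control),
    and ridge-regression connectome-based predictive modeling with nested
    cross-validation, permutation-null inference, and eigenvector-centrality
    region importance. A synthetic-cohort generator emulating the statistical
    structure of a longitudinal cognitive-aging study makes the full pipeline
    testable without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    coda,
    digest,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
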