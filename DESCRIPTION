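Package: emonet
Title: Network Models of Emotion Episodes: Simulation, Duration Analysis, and Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the duration and dynamics of emotional episodes
    under a network model of emotions. Emotion components (appraisals, feelings,
    motivations, physiological changes, expressions) are modelled as binary nodes
    of a pairwise (Ising-type) network with symmetric coupling weights and
    per-component thresholds. The package simulates stochastic Glauber dynamics
    under a fading external event, detects the end of an emotional episode as the
    first return of intensity to baseline, computes the exact stationary
    distribution of intensity by state enumeration, provides a common-cause
    comparator model, estimates networks from cross-sectional binary data by
    nodewise L1-penalized logistic regression with extended-BIC model selection,
    and generates synthetic networks and data sets with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
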