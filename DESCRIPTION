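Package: rewardmaps
Title: Spatial and Predictive Cognitive Maps for Reward Generalization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Models how agents generalize rewards across stimuli using
    Gaussian-process regression over two kinds of cognitive map: a spatial
    map (Gaussian kernel over Euclidean distances between stimulus locations
    estimated by path integration) and a predictive map (diffusion kernel
    over a transition graph recovered from a temporal-difference-learned
    successor representation). Includes a seeded synthetic world (arena,
    exploration policies, reward contexts, softmax GP agents), hierarchical
    logistic choice modeling with leave-one-trial-out cross-validation,
    random-effects Bayesian model selection with exceedance probabilities,
    trial-wise map-weight dynamics, model-derived parametric regressors for
    neuroimaging analyses, and bootstrap mediation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
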