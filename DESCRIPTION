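Package: cogsel
Title: Multi-Stage Feature Selection for Classifying Cognitive Aging Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating positive cognitive agers from cognitive
    decliners using high-dimensional, highly correlated feature tables such as
    structural-MRI morphometry. Implements a three-stage feature selection
    algorithm (mutual-information relevance filtering with greedy
    correlation pruning, an L1-regularized logistic-regression path with a
    smallest-adequate-C selection rule, and sequential forward selection tuned
    jointly with classifier hyperparameters by Bayesian optimization), a
    PCA-based General Cognition composite with quartile group labeling and
    trajectory slopes, a leakage-free benchmark harness for random-forest and
    support-vector-machine classifiers, and a seeded synthetic cohort
    generator with planted informative feature blocks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    e1071,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
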