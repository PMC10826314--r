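Package: rsmbo
Title: Response-Surface Designs and Constrained Bayesian Optimization for
    Bioprocess Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing classical design of experiments and
    response-surface methodology with adaptive Bayesian optimization on
    three-factor bioprocess studies such as alkaline wood delignification
    and hot-water carbohydrate extraction. Provides Box-Behnken and
    face-centered central composite design generation with G-efficient
    initialization subsets, hierarchical second-order regression with
    backward elimination and prediction diagnostics, Gaussian-process
    regression with a Matern-5/2 kernel and maximum-a-posteriori
    hyperparameters, a constrained noisy-expected-improvement optimization
    loop, simulation studies of initialization and measurement noise, and
    region-wise leave-one-out cross-validation for model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lhs,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
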