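Package: latentfc
Title: Latent-Variable Estimation of Intrinsic Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates state-general ("intrinsic") functional connectivity as a
    per-edge latent factor across multiple brain states. Each network edge's
    connectivity values over task and rest states are treated as indicators of a
    single latent variable; loadings, uniquenesses and regression-method factor
    scores are estimated independently for every edge, with a leave-one-state-out
    variant for non-circular held-out-state prediction. Includes activity-flow
    mapping of task activations from connectivity, behavioural (general
    intelligence) prediction via cross-sample ridge regression, Fisher-z
    similarity and meta-analytic inference utilities, construction of fMRI
    nuisance and finite-impulse-response design matrices, and a synthetic-data
    generator reproducing the framework's assumed statistical structure for
    fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
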