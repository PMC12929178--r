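Package: copanel
Title: Co-Developing Symptom Panels: Trajectory Classes and Cross-Lagged
    Panel Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-scale ordinal symptom panels measured
    over three waves (7 anxiety and 9 depression items scored 0-3), as used in
    longitudinal comorbidity studies. Provides scoring and binarization with a
    clinical cutoff, prevalence and comorbidity descriptives with trend
    chi-square tests, parallel-process latent growth modelling and latent-class
    growth analysis with class enumeration (information criteria, relative
    entropy, bootstrap likelihood ratio test), cross-lagged panel network
    estimation via nodewise penalized logistic regression with expected
    influence centrality, nonparametric bootstrap edge accuracy and
    case-dropping centrality stability, replicability comparison of two lagged
    networks, and a synthetic-data generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
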