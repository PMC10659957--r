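Package: jorospread
Title: Species Distribution Ensembles, Range-Expansion Metrics and
    Diversity-Impact Models for an Invading Orb Weaver
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for the early invasion of the Joro spider
    (Trichonephila clavata) in North America, reusable for other
    presence-background invasion studies. Provides occurrence cleaning with
    grid-based spatial thinning and background sampling; native-vs-introduced
    climate comparison by Mann-Whitney tests with rank-biserial effect sizes;
    correlation-guided predictor reduction; a four-model presence-background
    ensemble (GLM, GAM, a Maxent-equivalent penalized logistic model, and a
    down-sampled random forest) evaluated by spatial-block cross-validation;
    directional range-expansion estimation by leading-edge distances and
    kernel-density isopleth areas per quadrant; and transect diversity-impact
    models ranked by AICc with interaction-scenario predictions. A synthetic
    data module generates every input with known ground truth so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    glmnet,
    randomForest,
    vegan,
    MASS
Suggests:
    testthat (>= 3.0.0),
    ape,
    geosphere,
    pROC,
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
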