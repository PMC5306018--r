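Package: occAbund
Title: Two-Stage Occupancy-to-Abundance Modelling with Ensemble Species
    Distribution Models and Random-Forest Regression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts percent-cover abundance of plant species from
    plentiful presence-only occurrence records and scarce abundance
    surveys. Stage one converts presence-only records to presence-absence
    via a well-surveyed-site criterion, fits an ensemble of six species
    distribution model algorithms on repeated 70/30 splits, scores members
    by ROC AUC and the true skill statistic, selects a leading group or
    the top twenty, and combines survivors into a ROC-weighted ensemble
    occupancy map. Stage two harmonizes abundance records from two survey
    dialects into hectares covered per square kilometre and fits a
    random-forest regression of abundance on all species' predicted
    occupancy plus four tree-cover covariates, with a fold-count rule
    keeping an average of five nonzero records per cross-validation fold.
    A seedable virtual-species simulator generates spatially
    autocorrelated landscapes, zero-inflated abundance surfaces with
    biotic interactions, effort-dependent occurrence sampling and
    dual-dialect abundance surveys for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    mgcv,
    rpart,
    ranger,
    xgboost,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, Regression, Classification
RoxygenNote: 7.3.3
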