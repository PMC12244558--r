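Package: stacksdm
Title: Stacked Species Distribution Models for Gridded Richness Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ensemble species distribution modelling (SDM) toolkit for
    mapping species richness of benthic assemblages over gridded
    environmental layers. Covers preprocessing of an environmental stack
    (bilinear resampling, cropping, collinearity screening), cleaning and
    spatial thinning of presence-only occurrence tables, spatially
    stratified pseudo-absence sampling, per-species ensemble suitability
    models (classification trees, random forests, support vector machines
    and others) with k-fold cross-validation, threshold selection by
    maximising the true skill statistic, permutation variable importance,
    binary stacking into richness, uncertainty and weighted-endemism
    surfaces, regional and gradient diversity statistics (one-way ANOVA
    with Tukey HSD, OLS gradients, Moran's I), and clustering of species
    by importance profiles via PCA plus Ward hierarchical clustering. A
    virtual-species simulator with known niches supports end-to-end
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Matrix,
    rpart,
    randomForest,
    e1071,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    mgcv,
    nnet,
    withr
Config/testthat/edition: 3
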