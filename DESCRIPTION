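Package: stageniche
Title: Fine-Scale Life-Stage Ecological Niche Modelling with Abiotic and
    Biotic Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for fine-resolution ecological niche modelling of
    co-occurring life stages surveyed at nested spatial scales. Provides a
    seeded synthetic survey generator with stratified sampling points and
    nested quadrat grids; predictor screening by univariate GLMs, Spearman
    correlation filtering with scale competition, and sequential variance
    inflation factor dropping; presence-absence and abundance GLM
    calibration (binomial/quasibinomial, negative binomial/Poisson) with
    bidirectional stepwise AIC selection and Nagelkerke R-squared;
    internal (repeated 2-fold cross-validation) and external
    (cross-location) evaluation by AUC and Spearman rank correlation;
    cross-life-stage model transferability and asymmetric transferability;
    hierarchical partitioning of explanatory power into pure abiotic, pure
    biotic and joint components; and Moran's I permutation tests on model
    residuals with Holm correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    car,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
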