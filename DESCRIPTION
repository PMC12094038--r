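Package: thermofeed
Title: Body-Temperature Phenotypes and Feed Efficiency in Lactating Dairy Cows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking high-frequency vaginal body-temperature
    phenotypes (trial and daily means, consistency as log(var x 100),
    post-meal temperature change) to feed-efficiency traits (dry matter
    intake, secreted milk energy, metabolic body weight, residual feed
    intake) in lactating cows. Includes a synthetic herd generator with
    known ground truth, temperature quality control, meal-criterion
    estimation by maximum-likelihood mixture modelling of log10
    inter-visit intervals, milk-energy and metabolic-body-weight
    computation, residual-feed-intake modelling, temperature-humidity
    index covariates, cohort-adjusted association regressions, daily
    linear mixed models, and partial correlations controlling for cohort.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
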