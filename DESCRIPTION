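Package: oleohyst
Title: Hysteresis-Aware Selection of RGB Colorimetric Predictors for
    Olive Oil Accumulation Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Pipeline for predicting seasonal olive fruit oil concentration
    (% fresh weight) from RGB images. Segments fruit from a blue background,
    extracts mean Red/Green/Blue pixel values, computes 35 colorimetric
    indexes, quantifies the hysteretic oil-vs-index correlation with a
    loop-area index (Hyst), scores candidate predictors with a Fitness
    Index combining Hyst and Spearman's rho, fits benchmark 70/30
    resampled linear models with variance-inflation-factor collinearity
    control, and ranks models with a Global Performance Indicator built
    from normalized R-squared, RMSE and MAE. Includes a synthetic seasonal
    data generator (sigmoidal oil accumulation, rise-then-fall band
    trajectories, rendered multi-fruit image fixtures) so the whole
    analysis is reproducible without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    yaml,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    car,
    knitr,
    rmarkdown
Config/testthat/edition: 3
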