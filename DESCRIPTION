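Package: esrstack
Title: Early Prediction of the Erythrocyte Sedimentation Rate from Short
    Sedimentation Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the 60-minute erythrocyte sedimentation
    rate (ESR) from the first minutes of a blood column's sedimentation
    record. Includes a synthetic-cohort generator for normalized
    sedimentation curves and rendered syringe image stacks, an imaging
    pipeline (Otsu binarization, horizontal intensity profiles, single
    changepoint interface detection) that recovers the normalized column
    height over time, small multilayer-perceptron and recurrent (LSTM, GRU)
    forecasters trained with ADAM and early stopping, two-stage stacking
    ensembles over bootstrap resamples with mean, median, LASSO and partial
    least squares meta-combiners, repeated-evaluation protocols with MAPE
    and RMSE sweeps over input-window length and ensemble size, and
    statistical model comparison via the Friedman test with Nemenyi
    critical-distance post-hoc analysis and Bland-Altman agreement plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
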