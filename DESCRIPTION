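Package: hrbf
Title: Adaptive Self-Learning Bayesian Filtering of Wearable Heart-Rate Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Smoothing of heart-rate time series from wearable devices with an
    adaptive, self-learning Bayesian filter. The true heart-rate profile is
    modelled as an integrated random walk and the measurement noise as a
    stationary autoregressive process; within each analysis window the
    regularization parameter (the noise-to-signal variance ratio) is selected
    automatically by a maximum-likelihood criterion, so the filter tracks
    changes of the signal-to-noise ratio over time. Includes tools to fit and
    validate the autoregressive noise model (AIC order selection, whiteness
    testing), a synthetic benchmark generator with known ground truth and
    time-varying noise level, moving-average and LOESS comparator smoothers,
    and an evaluation harness (RMSE, MAE, MARD with day/night stratification
    and paired residual tests).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
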