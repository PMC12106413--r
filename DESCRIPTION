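Package: phytofuse
Title: Hybrid Mechanistic-Neural Forecasting of Soil Pollutant Remediation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasts soil pollutant concentrations during phytoremediation by
    fusing a mechanistic first-order soil-plant kinetics simulator, a
    feed-forward neural network, and a multi-head scaled-dot-product attention
    encoder with convex weights optimized on validation data. Includes a seeded
    synthetic-data generator for agricultural monitoring scenarios
    (decay kinetics with environmental forcing, observation noise, missing
    values), the preprocessing protocol (gap interpolation, Z-score
    standardization, fixed-length windowing, chronological splits), training by
    gradient descent or Adam with exact backpropagation, and evaluation metrics
    for both prediction accuracy (MSE, RMSE, tolerance-band accuracy) and
    ecological restoration (soil fertility change, plant growth rate increase,
    Shannon diversity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    yaml
Config/testthat/edition: 3
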