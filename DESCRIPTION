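Package: canokin
Title: Canonical Neural Representations and Kinematic Decoding for Motor Cortex Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline decoding pipeline for primary motor cortex (M1) population
    recordings paired with 2D hand kinematics. Builds kinematics-coupled neural
    representations via linear and deep canonical correlation analysis alongside
    unsupervised baselines (PCA, factor analysis, linear dynamical system latent
    states), and decodes hand velocity with a steady-state linear Kalman filter,
    a neural dynamical filter, or an LSTM sequence regressor. Includes a
    synthetic reaching-session simulator with known cosine-tuned ground truth so
    every stage has parameter-recovery tests, plus tuning-quality and decoding
    -error evaluation with Friedman/Wilcoxon method comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
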