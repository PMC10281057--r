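Package: drumkin
Title: Arm Kinematics and Permutation Inference for Wrist-Worn Drumming
    Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes two digital biomarkers of upper-limb motor function --
    average arm velocity and average arm-elevation angle -- from wrist-worn
    accelerometer and gyroscope streams recorded during group drumming
    sessions, and relates them to cognitive and motor measures in small
    cohorts.  Provides a documented CSV dialect for 20 Hz inertial streams,
    gravity-referenced orientation estimation with lever-arm compensation,
    rest-period filtering, permutation tests of Spearman rank correlations
    (exhaustive for very small samples), permutation multiple regression
    with variance-inflation and AIC model-ladder diagnostics, and a
    synthetic-data module that generates both quasi-periodic forearm-swing
    sensor streams with analytic ground truth and Gaussian-copula cohorts
    with a specified rank-correlation structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Matrix,
    withr
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
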