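Package: mobilitytrt
Title: Test-Retest Reliability Analysis of Instrumented Mobility Tasks
Version: 0.1.0
Authors@R: person("Maryland", "Mobility Lab", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis pipeline for test-retest reliability of
    wearable-sensor instrumented mobility tasks (Timed Up and Go, cognitive
    TUG, and a 32-foot walk with turns). Generates synthetic six-axis inertial
    recordings with known ground truth, segments tasks into subtasks via
    gyroscope-integrated turn detection, extracts gait, turn and chair
    transition measures, computes agreement statistics (two-way absolute
    agreement intraclass correlation, standard error of measurement, minimal
    detectable change, relative change, Bland-Altman limits of agreement), and
    evaluates trial-wise diagnostic random-forest models with forward feature
    selection and cross-validated majority voting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
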