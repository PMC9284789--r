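Package: dtrtplan
Title: Geometry-Based Trajectory Planning and QA Metrics for Dynamic
    Trajectory Radiotherapy
Version: 0.1.0
Authors@R:
    person("dtrtplan", "maintainers", email = "dtrtplan@example.org",
           role = c("aut", "cre"))
Description: Tools for geometry-based planning of dynamic trajectory
    radiotherapy (DTRT) on C-arm linacs: beam's-eye-view target/OAR
    overlap cost maps over gantry-table angle space, analytic
    collision and CT-scan-length exclusion modelling, gradient-
    constrained A* path-finding for gantry-table and collimator-gantry
    trajectories with moving-average smoothing and path duplication
    (field splitting or a constant 90 degree collimator offset),
    plan-quality metrics (DVH, dose-volume endpoints, Paddick
    conformity index, homogeneity index), global gamma-index dose
    comparison, and delivery-log mechanical-accuracy analysis.
    Includes a synthetic head-and-neck-like phantom generator so the
    full pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
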