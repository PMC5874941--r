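Package: gantrycam
Title: Camera-Based Time-Resolved Gantry Angle Quality Assurance for VMAT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linac-independent measurement of the radiotherapy gantry angle as a
    function of time from video footage of a two-dot fiducial pattern ("Double
    Dot") attached to the gantry face. Implements the per-frame dot-detection
    chain (channel isolation, median denoising, global thresholding, connected
    component centroids), angle determination with self-calibration, trajectory
    assembly, parsing and writing of DynaLog-style machine logs, synchronization
    and circular deviation statistics between trajectories, a synthetic scene
    renderer with a parameterized camera-noise model, and generators for three
    dynamic gantry QA test plans (constant speed, speed transitions, maximum
    inertia overshoot).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
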