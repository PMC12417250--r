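Package: exploretrace
Title: Trajectory-Based Exploration Phenotyping for Virtual-Environment
    Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts thirteen trajectory-based exploration measures (path
    length, pausing, area covered, roaming entropy, landmark visits and
    revisits, revisiting, turnarounds, flight turnarounds, fractal
    dimension, sinuosity, area and landmark efficiency) from timestamped
    movement logs recorded in bounded virtual environments, derives three
    compound exploration dimensions (activity, shape, efficiency) by
    hierarchical clustering of the standardized measures with kneedle knee
    detection, and compares the dimensions across sex and age with a mixed
    repeated-measures ANCOVA (Greenhouse-Geisser corrected), Bonferroni
    post-hoc t-tests, age correlations, and a BIC-approximated Bayes
    factor. A correlated-random-walk simulator with controllable
    demographic effects generates complete synthetic studies so the whole
    pipeline is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    lme4,
    MASS,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
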