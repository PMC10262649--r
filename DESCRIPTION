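Package: mazenet
Title: Barnes Maze Trajectory Scoring, Strategy Classification and
    Exploration-Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores rodent Barnes-maze trials from 2-D tracking
    trajectories sampled at a fixed frame rate on circular arenas of one
    or more scales. Computes conventional spatial-learning features
    (errors, latency, travel distance, probe-test dwell profiles),
    exponential learning-curve fits y = alpha * exp(-beta * t),
    algorithmic navigation-strategy classification (spatial, serial,
    random), and exploration networks built from detected stops via the
    City Clustering Algorithm, with order, degree, density, clustering
    coefficient, shortest path, betweenness and closeness measures. A
    synthetic trajectory generator emulates strategy-dependent paths,
    pausing and home-base behavior so every stage is testable without
    animal data. Includes a nonparametric group-comparison harness with
    effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
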