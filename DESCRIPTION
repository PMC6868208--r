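Package: shoalmetrics
Title: Group-Level Behavioural Stress Metrics for Fish Shoals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying behavioural stress responses of fish
    shoals observed as groups rather than as isolated individuals. Computes
    per-frame proximity metrics (nearest-neighbour distances and their
    coefficient of variation, inter-individual distance, expanse, convex
    hull area), spatial metrics (thigmotaxis as centroid distance to the
    nearest tank wall), and social metrics from proximity-based binary
    association networks (network density, subgroup structure). Supports
    clip-level behaviour coding with rare-behaviour filtering and
    intra-observer reliability statistics (percent agreement, Cohen's
    kappa), correlation-based pruning of collinear metrics, and
    condition-difference testing via mixed-effects likelihood-ratio tests
    with Bonferroni correction. An agent-based shoal simulator generates
    complete synthetic studies (trajectories, behaviour tables, whole-body
    cortisol) with the statistical structure the analysis assumes.
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
    grDevices,
    igraph,
    jsonlite,
    lme4,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
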