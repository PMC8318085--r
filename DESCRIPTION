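Package: spatunits
Title: Spatial Firing Analysis of Single-Unit Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing sorted single-unit spike trains recorded
    while an animal forages in an open arena: occupancy-normalised firing
    rate maps, Skaggs spatial information, spatial coherence and sparsity,
    head-direction tuning curves, spatial autocorrelograms with grid
    scores, border scores, burst-train statistics, occupancy-matched
    spatial downsampling controls, and condition-level presence statistics
    (a Bayesian posterior over two binomial presence probabilities and
    Barnard's unconditional exact test). A synthetic-data module simulates
    foraging trajectories and place, grid, head-direction, border,
    nonspatial and burst-structured spike trains with known ground truth,
    so the whole pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
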