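Package: placerep
Title: Place-Field Repetition and Nonpositional Rate Modulation on a City-Block Maze
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for hippocampal place-cell recordings from
    rectilinear "city-block" maze foraging. Builds the maze region model
    (alleys, intersections, corridors), computes occupancy-normalized
    ratemaps, detects place fields by peak expansion and watershed
    splitting, classifies repeating cells and scores population-level
    orientation alignment (OAS) against a shuffle null, quantifies
    per-field directional rate modulation with Mann-Whitney tests and
    Gamma-family generalized linear models with spline time covariates,
    compares directionality across repeating field pairs by corridor
    relation, measures slow temporal rate dynamics and population-vector
    drift, and decodes travel direction (random forest) and position
    (linear regression) from ensemble activity. Includes a synthetic
    session generator (maze-graph foraging behavior plus
    inhomogeneous-Poisson place-cell spiking with directional gain and
    rate drift) so the full chain is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    splines,
    jsonlite,
    lmtest,
    randomForest,
    pracma
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
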