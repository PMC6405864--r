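Package: fibriltrace
Title: Model-Based Tracing and Quantification of Cellulose Fibrils in
    Electron Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of cellulose elementary-fibril geometry
    in electron tomograms of the wood cell wall. Fibril centerlines are
    modelled as parametric space curves (a helicoidal term plus a
    polynomial deviation) and fitted directly to tomographic density with
    a particle-swarm optimizer refined by a Nelder-Mead simplex, without
    prior segmentation. From the fitted curve sets the package computes
    nearest-neighbour distances, orientation angles with respect to the
    anatomical planes and axes of the cell wall, bundle membership, and
    spatial grid maps. A synthetic phantom-tomogram generator (soft
    tubes, additive noise, optional missing-wedge anisotropy) provides
    ground truth for recovery experiments, and a config-driven pipeline
    orchestrates generation, preparation, fitting and metrics with full
    seeded determinism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    tiff,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
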