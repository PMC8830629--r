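Package: connscape
Title: Multi-Extent Niche Modeling, Resistant-Kernel Connectivity and
    Conservation Gap Analysis on Raster Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end landscape-connectivity workflow for
    presence-only wildlife data: multi-scale (focal-extent) habitat
    suitability modeling with a ridge-penalized presence-background
    logistic ensemble, suitability-to-resistance transformation,
    resistant-kernel and factorial least-cost-path connectivity on an
    8-neighbour cost lattice, core-habitat delineation with landscape
    pattern metrics (PLAND, NP, LPI, correlation length), graph-theoretic
    patch prioritization via the probability of connectivity index (PC,
    dPC and its intra/flux/connector fractions), and protected-area gap
    analysis. Includes a synthetic-landscape generator with known ground
    truth so the full pipeline is testable without external geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    glmnet,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
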