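Package: epiforce
Title: Non-Invasive Inference of Membrane Tensions and Cell Pressures in
    Epithelial Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers intercellular membrane stresses and relative
    intracellular pressures from segmented two-dimensional microscopy of
    epithelial tissues, without perturbing the sample. Segmentations
    (skeletonized membranes or labeled cell masks) are converted to a
    polygonal tissue graph; force balance at tricellular junctions yields
    a constrained least-squares system for membrane tensions, in a static
    (mechanical equilibrium) or dynamic (overdamped, velocity-augmented)
    mode, and the Young-Laplace relation then yields relative cell
    pressures. A native quasistatic vertex-model generator produces
    synthetic tissues with known tensions and pressures for validation,
    together with scoring utilities (MAPE, saturated score, scale-parameter
    sweep) and downstream analysis helpers (membrane-intensity profiles,
    pressure-weighted density, laser-ablation recoil fits).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    pracma,
    jsonlite,
    signal,
    igraph,
    optparse
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'analysis.R'
    'circle-fit.R'
    'dynamic-solver.R'
    'epiforce-package.R'
    'mesh-core.R'
    'raster-io.R'
    'read-mask.R'
    'read-skeleton.R'
    'run.R'
    'scoring.R'
    'solver-core.R'
    'synthetic-condition.R'
    'synthetic-export.R'
    'synthetic-relax.R'
    'synthetic-voronoi.R'
    'utils.R'
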