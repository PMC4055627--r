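Package: arcforce
Title: Cellular Force Inference from Curved Cell Boundaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers relative cell-edge tensions and intracellular pressures in
    planar epithelial monolayers from segmented images or mesh files, using
    circular-arc ("polyarc") representations of cell-cell boundaries. Circular
    arcs are fitted to each edge, limiting tangent angles at junctions enter
    overdetermined force-balance equations, and Laplace relations between
    tension, curvature and pressure differences provide a second equation
    system. Both systems are solved as constrained least-squares problems
    under mean-one tension and mean-zero pressure normalizations, yielding
    Standard Tensions and Standard Pressures together with quality
    diagnostics (condition numbers, residuals, standard errors). A forward
    simulator generates annealed synthetic epithelia with known ground-truth
    forces for validation, including measurement-noise injection and a
    rasterize/re-digitize protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    igraph,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
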