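Package: diffdim
Title: Diffusion-Based Relative, Local and Global Dimension of Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the dimension of a network from the transient response of
    a diffusion process governed by the random-walk normalized Laplacian. The
    peak time and amplitude of the heat-kernel response at each node, inverted
    through the Euclidean Green's function, yield a relative dimension between
    node pairs; averaging over targets that have peaked before a scale tau gives
    a scale-dependent local dimension per node, and its node average a global
    dimension curve whose maximum recovers the Euclidean dimension of grid-like
    graphs. Includes synthetic graph generators (lattices, Delaunay meshes with
    mass clusters, random-graph ensembles), an event-driven SIR module relating
    local dimension to node infectiousness across transmission rates, and a
    random-graph classification experiment on local-dimension distribution
    features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    deldir,
    randomForest,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
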