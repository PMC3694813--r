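Package: ecdyn
Title: Essential Collective Dynamics Analysis of Molecular Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Characterizes correlated protein motion from molecular-dynamics
    trajectories with the essential collective dynamics (ECD) framework:
    per-segment principal component analysis of Cartesian fluctuations, atom
    images in the space of essential collective coordinates, dimensionless
    pair-correlation maps, per-residue flexibility profiles with
    across-segment uncertainties, nearest-neighbor clustering into dynamic
    domains, comparison of computed flexibility against crystallographic
    B-factors, and distance-cutoff classification of inter-molecular
    interface contacts. Ships an overdamped-Langevin elastic-network
    trajectory generator with analytically known equilibrium covariance so
    every stage of the pipeline is testable without external simulation
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
biocViews: StructuralBioinformatics, PrincipalComponent, Clustering
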