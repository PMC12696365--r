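Package: silktube
Title: Geometric, Surface and Scattering Analysis of Tubular Spidroin
    Conformers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of coarse-grained bead models of intrinsically
    disordered spider silk proteins (spidroins). Extracts a curvilinear
    tubule axis from windowed centres of mass, computes hierarchical size
    metrics (averaged contour length, maximum Euclidean extent, tube
    radius, radius of gyration, Kirkwood hydrodynamic radius) and
    classifies conformer shape; partitions residues into buried,
    intermediate and exposed classes by rolling-ball solvent
    accessibility on bead spheres and compares the result with a
    continuum cylinder-shell packing model; computes Debye scattering
    curves, Guinier and Kratky analyses, and fits weighted conformer
    ensembles to experimental small-angle X-ray scattering profiles with
    a genetic algorithm; staples terminal-domain structures onto core
    chains and builds template-based dimers by rigid superposition; and
    segments spidroin sequences into amphiphilic blocks with generators
    for the standard mutant series. Includes synthetic structure and
    scattering generators with closed-form ground truth so every stage
    is testable without molecular dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
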