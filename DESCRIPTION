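Package: enmpath
Title: Elastic Network Model Energy-Response Profiling and Residue Path
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained Gaussian/elastic network model (GNM) analysis of
    C-alpha protein structures. Builds the contact (Kirchhoff) matrix from a
    C-alpha trace, eigendecomposes it, and computes mode-restricted residue
    fluctuation correlations, predicted B-factors, inter-residue distance
    fluctuations, and a per-residue energy-response profile whose fast-mode
    peaks mark energetically responsive (hotspot) residues. Provides contact
    graph construction and shortest energy-conduction path extraction between
    residues, permutation tests for overlap between hotspots and residue
    conservation levels, sliding-window peptide library generation for
    docking campaigns, and conversion of binding free energies to
    dissociation constants. Includes a synthetic C-alpha trace generator
    (linear chains, ideal helices, perturbed lattices) for testing every
    stage without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
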