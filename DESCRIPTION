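Package: gpcrpocket
Title: GPCR Orthosteric Pocket Geometry, Volume Restraints and Ensemble Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for measuring and controlling the size of the orthosteric
    ligand-binding pocket of class A G protein-coupled receptors (GPCRs).
    Defines the pocket through generic residue positions
    (Ballesteros-Weinstein / GPCRdb numbering), measures its volume as the
    convex-hull (Delaunay tessellation) volume over ten surrogate alpha-carbon
    positions, aggregates pairwise alpha-carbon distance statistics over
    structure sets, detects ligand-contacting pocket residues, generates
    two-tetrahedron AtomPair distance restraint sets in the Rosetta
    constraint-file dialect with randomized parameters, evaluates the
    harmonic restraint potential, and filters and ranks model ensembles by
    pocket volume and score. Includes a synthetic seven-transmembrane bundle
    generator for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
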