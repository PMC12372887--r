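Package: kinconform
Title: Kinase Conformational Geometry, Conservation Mapping, and Binding
    Model Fits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing protein kinase inhibitor selectivity and
    structure. Partitions kinome-panel remaining-activity tables into
    inhibited and non-inhibited groups, computes ConSurf-style 1-9 residue
    conservation grades from kinase-domain alignments with bootstrap
    confidence flags, screens for group-differential conservation mapped to
    reference residue numbering, measures the geometric quantities that
    define kinase conformational states (DFG D1/D2 distances, Lys-Glu salt
    bridge, x-DFG-x backbone dihedrals, disulfide bridges, regulatory-spine
    contacts, rigid superposition), classifies DFG-in/out and alphaC
    in/out states, and fits one-site total binding and variable-slope
    dose-response models. Includes seeded synthetic-data generators (panel
    tables, alignments, three-dimensional models with planted geometry,
    noisy curves) so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
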