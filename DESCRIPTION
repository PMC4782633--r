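Package: septamodal
Title: Prestressed Modal Analysis and Deviation-Type Classification of the Nasal Septum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element modal analysis of an idealized cartilaginous
    nasal-septum plate.  Builds a parametric midplane outline with labelled
    bony interfaces, meshes it with linear triangles, assembles decoupled
    membrane (constant-strain triangle) and bending (discrete Kirchhoff
    triangle) operators with rigidly fixed bony edges and an optional
    grounded tip spring, solves a static in-plane preload step, forms the
    geometric (initial-stress) stiffness, extracts the lowest natural
    frequencies and mode shapes of the prestressed plate, and classifies
    each mode as a septal tilt (type I), C-shape (type II), S-shape
    (type III) or in-plane mode from the sign structure of the transverse
    displacement field.  Modal von Mises stress hotspots are mapped to
    anatomical landmarks (anterior nasal spine, bony-cartilaginous
    junction, vomer-ethmoidal junction, vomerine groove).  Includes a
    seeded generator of patient-like outline and thickness perturbations
    and analytic plate fixtures for solver validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
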