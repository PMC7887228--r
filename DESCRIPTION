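Package: minicircler
Title: Topology, Defect, Energetics and AFM Morphometrics Analysis of
    Supercoiled DNA Minicircles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the geometry and topology of closed-circular
    (minicircle) DNA: helical-axis contour extraction, bend-angle profiles and
    kink/defect classification, the Gauss-integral writhe and the twist-writhe
    partition of the linking number, planarity and aspect-ratio shape metrics,
    a screened-Coulomb decomposition of triplex (third-strand) binding
    energetics, and an automated atomic force microscopy (AFM) height-image
    pipeline (flattening, masking, grain filtering, morphometrics, molecule
    tracing and protrusion localisation). All analyses are exercised on
    synthetic inputs of known ground truth generated by the package itself:
    closed ribbons of prescribed linking number, pseudo-atomic minicircle
    models with planted kinks, denaturation bubbles and triplex third strands,
    and simulated AFM topographs with tip broadening, scan-line offsets, plane
    tilt and noise.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
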