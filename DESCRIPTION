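Package: pronomorph
Title: Geometric Morphometrics of Pronotum Outlines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Outline-based geometric morphometrics for comparing pronotum
    shape across extant and fossil ice-crawler (Grylloblattodea) genera:
    reading and writing the TPS digitizing format, arc-length-equidistant
    semilandmark resampling of closed outlines, generalized least-squares
    Procrustes superimposition, tangent-space approximation diagnostics,
    thin-plate-spline bending energy and deformation, relative warps by
    singular-value decomposition of the weight matrix, principal-coordinates
    ordination, and UPGMA phenograms from Procrustes distance matrices.
    Includes a seeded synthetic outline generator that emulates a
    28-specimen, 13-genus study design with genus-level mean shapes,
    species-level shape noise and nuisance similarity transforms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
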