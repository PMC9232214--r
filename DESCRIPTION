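Package: painmap
Title: Pain Frequency Maps from Grid-Free Freehand Pain Drawings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies freehand pain drawings made on grid-free 2D body
    templates. Drawings are captured as overlapping axis-aligned squares
    (SVG rect elements); the package decomposes any number of participants'
    rectangles into maximal nonoverlapping rectangles, each annotated with
    the set of participants whose drawings cover it, its overlap frequency
    and its overlap proportion, and renders the result as an opacity-coded
    pain frequency (heat) map on a body-template SVG. Includes SVG/CSV
    extraction with eraser and duplicate semantics, simulation workloads
    for benchmarking, a brute-force raster oracle for validation, and a
    chainable command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    xml2,
    grDevices,
    graphics,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
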