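Package: plotalign
Title: Field-Plot Grid Alignment for Aerial Orthomosaic Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic extraction of agronomic field plots from aerial
    orthomosaic images. A coarse uniform grid of fixed-size rectangular cells
    is refined by per-cell displacements that maximise the vegetation-index
    mass captured inside each cell while penalising overlap between
    neighbouring cells; the resulting bound-constrained cost is minimised
    with an adaptive particle swarm optimizer. Includes a green-red
    difference vegetation index, summed-area-table energies, a synthetic
    trial-image generator with known ground-truth displacements, alignment
    error and canopy-coverage evaluation with one-way ANOVA, scripted
    validation experiments, and plain TIFF/PNG/JPEG and ESRI shapefile
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Rcpp,
    png,
    jpeg
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
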