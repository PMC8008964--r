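Package: scPies
Title: Pie-Chart Glyph Visualization of Single-Cell Embeddings
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Renders every cell of a two-dimensional single-cell embedding
    (UMAP, t-SNE, or any coordinate export) as a pie-chart glyph whose slices
    show the proportional expression of one or more marker gene lists in that
    cell. Gene lists of unequal length are weighed equally through a
    list-size normalization of expression values; slice color intensity and
    glyph size encode expression magnitude. Includes automatic color
    assignment from colormaps, legend generation, a cluster-aggregated
    "big pies" mode showing average expression per cluster sized by cell
    count, deterministic SVG/PNG rendering, readers for delimited and
    MatrixMarket expression exports, a synthetic single-cell data simulator
    for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    xml2,
    knitr,
    rmarkdown
biocViews: SingleCell, Visualization, Transcriptomics, DimensionReduction
Config/testthat/edition: 3
RoxygenNote: 7.3.3
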