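Package: igan
Title: Intercellular Gene Association Networks for Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs gene-gene association networks between spatially
    adjacent cell (or spot) pairs from spatial transcriptomics data, using a
    local-neighborhood independence test on cell-pair expression scatters.
    On top of the per-pair binary association networks it computes per-cell
    ligand sending/receiving activity and overall cell-cell communication
    strength, assembles panoramic ligand-receptor-pathway (Sankey) graphs,
    clusters cells on communication features, and benchmarks communication
    patterns against spatial microenvironment patterns via paired
    non-negative matrix factorization and a weighted Kullback-Leibler
    consistency score. Includes a synthetic-data generator with planted
    intercellular couplings for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    mclust,
    methods,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
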