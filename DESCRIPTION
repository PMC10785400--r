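Package: voxdock
Title: Consensus Blind Docking via Voxel-Grid Aggregation of Docking and
    Cavity Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Aggregates ligand poses from several blind-docking programs and
    pocket predictions from cavity-detection tools onto a 10 Angstrom voxel
    grid over a protein, scores each occupied voxel with a feature-selected
    stacked classifier, and predicts the ligand binding site as the cavity
    nearest the top-scoring voxel. Includes Boruta shadow-feature selection,
    bagged multi-layer stacked ensembling, symmetry-corrected ligand RMSD
    via molecular-graph automorphisms, distance/accuracy benchmark metrics,
    parsers for common docking and cavity-tool output formats, a versioned
    JSON interchange format, and a synthetic scenario generator so the whole
    pipeline can be trained and evaluated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    pROC,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
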