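Package: otomove
Title: Movement History Reconstruction from Otolith Elemental Transects
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct within-river movement histories of
    facultative amphidromous fish from laser-ablation ICP-MS otolith
    transects. Provides transect ingestion with detection-limit filtering,
    manganese-peak core detection and chronological re-orientation,
    multivariate chronological segmentation by recursive binary partitioning,
    ensemble-classifier (random forest) element selection and partition
    location prediction with out-of-bag evaluation, movement and life-history
    classification (freshwater resident, estuarine resident, amphidromous),
    permutational multivariate analysis of variance (PERMANOVA) on edge
    elemental fingerprints, and a synthetic cohort generator that makes every
    stage of the pipeline verifiable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
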