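Package: caviclass
Title: Classification of Caveolae and Scaffolds from 3D SMLM Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a segmented 3D cluster ("blob") of
    caveolin-1 localizations from single molecule localization microscopy
    (SMLM) is a caveola or a non-caveolar scaffold. Implements the full
    workflow: eventlist ingestion, iterative localization merging, density
    based noise filtering, blob segmentation, CAVIN1/PTRF mask labeling and
    class balancing; three blob representations (a 28-value hand-crafted
    morphological/network feature vector, three orthogonal binary
    projections, and the raw point cloud); a bagged random-forest classifier
    plus compact multi-view CNN and PointNet-style neural classifiers; the
    evaluation protocol (mixed and cell-wise splits, stratified k-fold cross
    validation, confusion-matrix metrics); and a fully specified two-class
    multivariate-normal blob simulator used for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    igraph,
    randomForest,
    Rtsne,
    EBImage,
    png,
    tiff,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS
Config/testthat/edition: 3
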