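Package: netpls
Title: Network-Based RBF Sparse Partial Least Squares for Imaging and
    Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint dimension reduction and sparse regression for studies that
    pair high-dimensional 3D image panels (e.g. voxel-based morphometry maps)
    with tabular biomarker panels. Images are compressed with a compactly
    supported radial B-spline basis on a knot lattice, biomarkers are reduced
    by estimating a statistical dependency graph, finding overlapping link
    communities and keeping one representative variable per cluster (highest
    information centrality, or highest variance for two-node clusters). The
    two reduced matrices are linked by a sparse partial least squares model
    with L1-penalized weight vectors, penalties tuned by 5-fold PRESS
    cross-validation; components relevant to a binary diagnosis are then
    selected by backward-stepwise BIC logistic regression on the component
    scores. Includes a synthetic-data generator with full ground truth and a
    bootstrap evaluation harness comparing clustering-based reductions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    glmnet,
    mclust,
    RNifti,
    stats,
    utils,
    methods,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
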