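Package: unfoldcoords
Title: Topological Unfolding of Hippocampal Grey Matter
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes an intrinsic coordinate system over hippocampal grey
    matter from a voxel tissue-class labelmap: Laplace fields along the
    anterior-posterior, proximal-distal and inner-outer axes, an optional
    equivolumetric laminar depth, dense bidirectional warps between native
    and a standardized unfolded space, folded and unfolded surface meshes
    with vertex correspondence, topologically constrained subfield labels,
    vertex-wise morphometry (thickness, curvature, gyrification), template
    shape injection for segmentation regularization, a parametric
    folded-sheet phantom with analytic ground truth, and Dice-based quality
    control flagging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    Matrix,
    igraph,
    xml2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
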