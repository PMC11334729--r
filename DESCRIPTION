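Package: gmnet
Title: Single-Subject Gray Matter Networks and Small-World Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds individual morphometric brain networks from gray-matter (GM)
    volume images: each image is partitioned into non-overlapping 3x3x3-voxel
    cubes (nodes), inter-cube Pearson similarities are binarized by
    Benjamini-Hochberg FDR control, and global graph metrics (size, degree,
    connectivity density, clustering coefficient, characteristic path length)
    together with small-world coefficients (gamma, lambda, sigma) are computed
    against degree-preserving random reference graphs. Includes a synthetic
    cohort generator (three diagnostic groups with calibrated demographics and
    spatially covarying 3D GM volumes), covariate-adjusted group statistics with
    FDR-corrected pairwise tests, metric-cognition regressions, and voxel-wise
    partial-correlation mapping between the small-world coefficient and GM
    volume with permutation-based cluster correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
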