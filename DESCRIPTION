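Package: dentreg
Title: Automatic Registration of Dental CBCT Volumes and Colored Intraoral Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for aligning colored intraoral scan surfaces to cone-beam
    computed tomography (CBCT) volumes of the dentition. The pipeline
    segments teeth from the CBCT volume using per-slice masks, a dental arch
    curve and a panoramic reprojection that separates upper from lower jaw,
    extracts tooth crowns from colored intraoral scans by HSV-space
    k-nearest-neighbour classification, and registers the two point clouds
    by RANSAC coarse alignment over fast point feature histograms followed
    by point-to-plane ICP refinement. Includes validation metrics (nearest
    neighbour distance statistics, chamfer and Hausdorff distances,
    Bland-Altman agreement of coronal cross-section areas, error color
    maps) and a synthetic dental phantom generator with exact ground truth
    for benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    yaml,
    jsonlite,
    png,
    tiff,
    grDevices,
    graphics,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
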