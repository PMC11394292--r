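Package: ovicloud
Title: Three-View Point-Cloud Reconstruction and Body Measurement of Sheep
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstruction of sheep bodies from multi-view depth-camera
    point clouds and non-contact measurement of body dimensions. Provides
    ASCII PLY/PCD/XYZ input and output, pinhole depth-image back-projection,
    passthrough and statistical outlier filtering, RANSAC ground-plane
    segmentation, a density-conditioned voxel-centroid downsampling filter,
    cubic-spline repair of occlusion holes, coarse-to-fine rigid registration
    (correspondence RANSAC with SVD transform solving, refined by iterative
    closest point), PCA rotation normalization, robust body-length
    measurement with accuracy evaluation against tape measurements, and a
    synthetic three-camera sheep-scene generator with full ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
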