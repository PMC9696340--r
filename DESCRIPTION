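Package: dissolvis
Title: In Situ Visualization and Quantification of Tablet Dissolution from
    Time-Resolved X-ray Micro-CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify water penetration into sustained-release
    tablets from time-resolved X-ray micro-computed tomography (4D uCT)
    acquired in a contrast-agent (CsCl) brine flow cell, and to relate it
    to the drug-release profile measured by UV spectrophotometry. Covers
    the full analysis chain: a synthetic 4D tablet phantom with known
    ground truth (Beer-Lambert attenuation, shrinking-core ingress,
    reconstruction shading artifacts), multi-page TIFF volume I/O with a
    JSON manifest, bilateral filtering, threshold + connected-component
    segmentation, voxel-counting porosity, rigid registration and
    resampling, VOI erosion, per-timestep histogram analysis with
    two-Gaussian intersection thresholding, k-nearest-neighbour wet/dry
    voxel classification on coordinate/gray/distance-transform features,
    UV calibration, cumulative-release accounting with withdrawal
    correction, the f2 similarity factor, and an end-to-end reproducible
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
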