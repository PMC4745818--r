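Package: aortaseg
Title: Automatic Ascending-Aorta Segmentation from 3D Cardiac CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic segmentation of the ascending aorta from
    contrast-enhanced cardiac CT volumes. A circular Hough transform detects
    candidate aortic cross-sections on every axial slice, a circle-stability
    energy selects the most consistent ascending circle across an 11-slice
    window, and a seeded geodesic-distance transform (squared-gradient edge
    weights, multi-pass raster-scan propagation) segments each slice inside a
    volume of interest. Seeds are transferred to neighbouring slices by
    distance-to-border thresholds until they are exhausted, yielding a 3D
    binary mask. Includes a synthetic tube phantom generator with known
    ground truth, Dice overlap evaluation, isosurface mesh extraction,
    NIfTI, NRRD and DICOM-series readers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
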