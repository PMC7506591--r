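Package: rwcontour
Title: Semi-Automated Thoracic Organ Contouring with Random Walks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seeded multi-label random-walker segmentation of thoracic CT
    volumes for radiotherapy organ-at-risk contouring. Segments the lungs,
    airway, heart, spinal cord, body outline and gross tumor volume from a
    single manually seeded slice, propagating seeds slice-by-slice through
    the volume with boundary-erosion and skeleton sampling plus a
    Hounsfield-unit knowledge filter, refining the spinal cord with a Hough
    circle fit, and evaluating contours with Dice, false-positive/negative
    rates and Hausdorff distance. Includes a synthetic thoracic phantom
    generator with ground-truth masks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    EBImage,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
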