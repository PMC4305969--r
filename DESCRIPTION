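Package: lobulaR
Title: Object-Based Detection of Mammary Lobules and Nuclear Hormone-Receptor
    Positivity in Brightfield Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects normal mammary gland lobules and coherent tumor mass in
    downsampled brightfield whole-slide images by texture-weighted
    multiresolution region-merging segmentation and rule-based hierarchical
    classification, then quantifies DAB-positive versus hematoxylin-negative
    nuclei per lobule at full resolution via hue-saturation-density stain
    deconvolution, watershed splitting, and concavity-based cutting of merged
    nuclei. Relates per-lobule nuclear positivity to distance from the tumor
    border in adjacent/intermediate/distant bins. Includes a calibrated
    synthetic-slide generator with ground truth, a minimal baseline TIFF/PNM
    codec, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
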