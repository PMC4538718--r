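Package: ssphantom
Title: Digital Subresolution-Sandwich Phantoms for Benchmarking PET
    Auto-Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates digital analogues of printed subresolution-sandwich
    PET phantoms: ground-truth 3D FDG uptake templates for spherical,
    spheroidal and irregular lesions with homogeneous, two-level, Gaussian,
    necrotic and necrotic-Gaussian uptake patterns; a simplified PET
    simulator (volume-conserving resampling, Gaussian point-spread blur,
    Poisson counting noise); printer calibration mathematics (cubic
    grey-to-ink and linear ink-to-counts fits with decay correction and
    numerical inversion); ten automatic PET segmentation methods (adaptive
    iterative thresholding, iterative region growing, fuzzy C-means with
    Gaussian mixture weighting for 2 to 8 clusters, and slice-by-slice
    marker-based watershed); and overlap-metric evaluation (Dice,
    sensitivity, positive predictive value) with a config-driven experiment
    runner.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    pracma,
    RNifti,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
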