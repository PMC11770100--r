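Package: LarvaScreen
Title: Automated Cardiac Phenotyping and Dosing Toolkit for Zebrafish Larva Screening
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Image-analysis and dosing toolkit for automated in vivo screening of
    zebrafish larvae in microfluidic channels. Implements the computer-vision chain
    for larva presence detection, eye segmentation and head/tail orientation calls;
    the cardiac quantification pipeline (band-pass filtered region-of-interest
    heart-rate estimation, M-mode wall-motion matrices, ellipse fitting of the
    ventricular edge, and fractional area change, stroke volume and cardiac output
    from end-diastolic/end-systolic axis extrema); and the droplet dosing maths
    (injection-volume solver for target in-droplet concentrations and Beer-Lambert
    calibration fitting). Ships seeded phantom generators that render beating
    elliptical ventricles and larva silhouettes with full ground truth, so every
    stage can be validated end-to-end without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
biocViews: Software, CellBasedAssays, Visualization, Preprocessing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
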