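Package: omapr
Title: Cardiac Optical Mapping Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing and analysis of cardiac optical mapping movies:
    reading MAT-format fluorescence stacks, voltage-dye polarity handling,
    Gaussian spatial filtering with masked renormalisation, top-hat
    morphological baseline correction, automated beat and pacing-cycle-length
    detection with ensemble averaging, per-pixel action potential duration
    (APD), activation-time and APD-alternans maps, multi-vector conduction
    velocity estimation from local polynomial fits of activation surfaces,
    optical wave similarity, and dominant-frequency mapping.  Includes a
    kinematic synthetic-movie generator with exact ground truth so every
    stage of the pipeline can be validated without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
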