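Package: fiberweave
Title: Morphometry, Collagen Fiber Orientation and Entanglement Analysis for
    Skin Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying skin architecture from
    histology and second-harmonic-generation (SHG) microscopy. Computes
    strip-wise layer thickness profiles (stratum corneum, viable epidermis,
    dermis) from labeled histology masks; preprocesses SHG stacks (intensity
    clipping, Gaussian blur, exact rolling-ball background subtraction);
    quantifies SHG intensity over randomly placed regions of interest;
    extracts collagen fibers with a multiscale Hessian ridge filter and
    skeleton tracing, classifies their in-plane orientation relative to the
    skin's outward normal into perpendicular and parallel windows with a
    bimodality call; and counts fiber crossings per unit volume
    ("entanglement" density). A synthetic phantom generator with exact ground
    truth (layered masks, fibrous tubes from angular mixtures, planted
    crossings, paired intensity stacks) makes every stage verifiable without
    raw images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    car,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
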