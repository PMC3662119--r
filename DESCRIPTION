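Package: mammodensity
Title: Automated Area-Based Mammographic Percent Density and Agreement
    Statistics
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fully automated, area-based percent mammographic density
    estimation for "For Presentation" full-field digital mammograms
    (mediolateral-oblique views): breast-envelope masking (background,
    pectoral muscle, subcutaneous fat margin, overlay text), dense-tissue
    thresholding by the Kapur maximum-entropy and Tsai moment-preserving
    methods, and the dense-area to region-of-interest ratio with BI-RADS
    density categorisation.  Includes the complete rater-agreement
    evaluation toolkit (two-way random-effects intraclass correlation with
    F-based confidence intervals, quadratically weighted kappa, Pearson
    correlation, Bland-Altman limits of agreement, within-one-category
    agreement, per-category distribution summaries), a synthetic MLO
    phantom generator with exact ground truth, a minimal DICOM reader and
    writer, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
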