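Package: facefit
Title: Facial-Scan Driven Respirator Sizing and Seal-Leak Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a scan-to-respirator-size workflow. Reads triangular
    facial meshes (binary and ASCII STL), orients them into a reproducible
    anatomical frame from user-supplied landmarks, and extracts the facial
    parameters that drive semi-customised respirator selection: eye-to-chin
    distance and the amplitude and spread of a Gaussian fitted to the nasal
    cross-section profile. Builds the two-stage, full-width-at-half-maximum
    based nine-design sizing table from a cohort of extracted parameters,
    assigns individual users to a design or flags them for full
    customisation, and compares parameter sets from different scanning
    methods. A flow-visualisation module quantifies mask-seal leakage from
    high-speed greyscale footage by background subtraction, thresholding,
    despeckling and post-transient leak-slope fitting. Synthetic generators
    produce parametric faces, cohorts and leak videos with known ground
    truth so the full pipeline can be exercised without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    png,
    yaml,
    optparse,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
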