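Package: ghostgrade
Title: Quantitative Nystagmus Assessment from Fundus Photograph Ghost Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing nystagmus from single fundus photographs.
    Eye movement during the camera exposure duplicates retinal structures
    into "ghost" images; the displacement between copies encodes nystagmus
    amplitude and their orientation encodes direction. The package provides
    a synthetic fundus phantom and ghost-image simulator with known ground
    truth, autocorrelation- and vessel-landmark-based estimators of ghost
    displacement, rotation and image count, an ordinal 0-3 amplitude grade
    and direction classification, concordance statistics against clinical
    examination (detection rates, percent agreement, exact Mann-Whitney
    tests), longitudinal session comparison, and an end-to-end reproducible
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
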