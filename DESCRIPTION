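Package: stripeblend
Title: Distance-Dependent Conspicuousness of Striped Prey Through Avian Eyes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how the conspicuousness of a high-contrast striped
    target (such as an orange-and-black aposematic caterpillar on a green
    stem) changes with effective viewing distance. Generates synthetic
    calibrated photographs with known ground truth, recovers the camera
    nonlinearity from embedded reflectance standards, models tetrachromatic
    avian photoreceptor catches and a luminance/red-green/yellow-blue
    opponent colour space, emulates acuity limits by Gaussian pattern
    blending, and measures pixel-level target/background discriminability
    with binomial mixed models under leave-one-out cross-validation across
    scenes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    glmnet,
    stats,
    utils,
    withr,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
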