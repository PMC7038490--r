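Package: cloudtongue
Title: Fuzzy Linguistic Evaluation of Electronic-Tongue Taste Data via
    Two-Dimensional Normal Cloud Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Turns multichannel electronic-tongue potentiometric readings of
    Chinese liquor into human-style fuzzy evaluation sentences. Provides
    backward and forward normal cloud generators (expected value Ex, entropy
    En, hyper-entropy He) for taste-information concepts in a PCA-reduced
    two-dimensional plane, contribution-rate integrals of the cloud density,
    a genetic-algorithm-tuned radial-basis support vector machine for flavor
    classification, a standard-normal-quantile mapping from sensory-panel
    word frequencies to nested elliptical regions of the principal-component
    plane, a seeded synthetic-data generator that emulates the 4-flavor
    (jiang, feng, nong, mild) study design, and an end-to-end pipeline that
    composes the final evaluation language.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    pracma,
    stats,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
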