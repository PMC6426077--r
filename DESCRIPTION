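Package: meioscope
Title: Quantification of Meiotic Chromosome Segregation from Live-Cell
    Fluorescence Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for scoring meiotic chromosome segregation
    phenotypes in budding yeast from multichannel time-lapse fluorescence
    z-stacks: Yen auto-thresholding and connected-component spot detection,
    cross-channel intensity measurement at kinetochore footprints,
    inter-kinetochore line profiles with two-peak intensity scoring,
    securin-degradation anaphase-onset detection, per-cell phenotype calls
    (cohesin localization pattern, centromere-marker distance class,
    separase-biosensor state, division count, nuclear area ratio), and
    Welch-test reporting. Includes a stochastic per-cell simulator of
    genotype-dependent segregation outcomes and a synthetic movie renderer
    that together provide pixel-exact ground truth for validating every
    measurement stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tibble,
    dplyr,
    jsonlite,
    tiff,
    EBImage,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
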