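Package: wishtools
Title: Decomposition and Curation of Whole-Mount In Situ Hybridisation Images
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computational decomposition of whole-mount in situ
    hybridisation (WISH) photographs of Xenopus embryos. Locates the embryo
    against arbitrary backgrounds with a Gaussian-mixture model over two-scale
    colour and gradient features followed by Bayesian spatial model selection;
    unmixes histochemical stain from natural pigment and background
    bleed-through with hint-guided independent component analysis; classifies
    collections into cleared and un-cleared preparations; clusters
    quasi-spherical-stage images by expression-pattern similarity under affine
    alignment; and selects representative images from redundant collections.
    Includes a deterministic synthetic-image generator with exact ground truth
    used as the test bed, and the Beta-posterior error-rate and Wallace
    partition-agreement statistics used for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    mclust,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
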