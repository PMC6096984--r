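Package: vesicurv
Title: Curvature-Elastic Analysis of Light-Induced Vesicle Budding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis of light-triggered membrane area increase
    and budding of giant unilamellar vesicles (GUVs) within the spontaneous
    curvature / area-difference-elasticity framework.  Provides the
    closed-neck condition relating mother and bud radii to the local and
    nonlocal spontaneous curvature, limit-shape lines and morphology
    classification in the (reduced volume, dimensionless curvature) plane,
    membrane-area extraction from electrodeformation time series of prolate
    vesicles, quantification of photoswitch partitioning from size-exclusion
    chromatography elution traces, and seeded synthetic-data generators with
    known ground truth for end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
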