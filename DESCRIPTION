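Package: seasens
Title: Seabird Density Surfaces and Offshore Wind Farm Sensitivity Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating seabird density surfaces from segmented
    line-transect surveys (distance sampling with half-normal or hazard-rate
    detection functions, followed by spatial generalised additive density
    surface models on a 3 km x 3 km prediction grid), for scoring species
    sensitivity to offshore wind farm collision and displacement from ten
    conservation and behaviour factors, and for combining density surfaces
    with sensitivity scores into seasonal gridded sensitivity maps using
    coefficient-of-variation gated data fusion. Includes a synthetic survey
    generator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mgcv,
    MASS,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
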