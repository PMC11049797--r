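Package: beecolor
Title: Continuous Quantification of Honey Bee Abdominal Coloration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for objective, continuous-scale quantification of worker
    honey bee abdominal coloration from stereo-microscope images. Rectangular
    regions of interest are collapsed into fixed-length coloration profile
    vectors (per-column median gray values with saturated and desaturated
    pixels excluded), summarized as a single trapezoidal-area "coloration
    index", classified by incubation temperature with a linear support vector
    machine (optionally after UMAP dimensionality reduction), and analyzed
    with a Box-Cox / two-way ANOVA / Tukey HSD inferential chain. A synthetic
    abdomen-image generator with known group structure supports testing and
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    car,
    e1071,
    jsonlite,
    graphics,
    grDevices,
    pROC,
    png,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    uwot
Suggests:
    jpeg,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
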