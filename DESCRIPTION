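Package: viselect
Title: Integrated Vegetation-Index Feature Selection for UAV Yield Prediction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes a library of 35 multispectral vegetation indices from
    plot-level five-band reflectance (blue, green, red, red-edge, NIR),
    screens them for crop-yield prediction by combining a Pearson-correlation
    filter with random-forest permutation importance, refines the union of
    the two screened subsets by patience-limited recursive feature
    elimination over pluggable base regressors (a rule-based model tree and
    a recurrent-network regressor), and evaluates yield models by k-fold
    cross-validation. Ships a synthetic water-stress field-trial generator
    so selector recovery and pipeline behaviour can be benchmarked without
    access to field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
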