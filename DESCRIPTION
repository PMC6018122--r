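Package: droptex
Title: Texture Analysis of Dried-Droplet Deposit Micrographs
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative texture analysis for micrographs of deposits left
    by evaporating droplets of protein-salt solutions. Computes first-order
    histogram statistics (mean, standard deviation, integrated density,
    skewness, excess kurtosis) and gray-level co-occurrence (Haralick-style)
    features (energy, inertia, correlation, inverse difference moment,
    entropy) from 8-bit grayscale images; fits a saturating exponential
    response law to texture parameters measured across a condition series;
    classifies deposit groups by canonical discriminant analysis with
    sequential Wilks' lambda tests; tracks texture trajectories over
    evaporation image sequences and segments the three formation stages by
    exact least-squares change-point detection. Includes a seeded synthetic
    deposit-image generator so the whole pipeline can be exercised and
    validated without laboratory micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
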