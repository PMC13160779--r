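Package: gtwr
Title: Geographically and Temporally Weighted Regression for Region-Year Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatiotemporal regression toolkit for small region-year panels of
    incidence rates, built around geographically and temporally weighted
    regression (GTWR) with a Gaussian spatial kernel, an exponential temporal
    kernel, and AICc-driven bandwidth selection. Includes construction of
    Queen, Rook and k-nearest-neighbour spatial weights from polygon
    geometries, global and local Moran's I with permutation inference, a
    global OLS baseline with multicollinearity screening (VIF, LASSO) and
    heteroscedasticity diagnostics, a composite log-scale isolation index
    built from residential versus non-residential activity streams,
    underreporting sensitivity scenarios, standardized offset calculus, and a
    synthetic region-year panel generator with known spatially varying
    coefficient surfaces for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deldir,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    car,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
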