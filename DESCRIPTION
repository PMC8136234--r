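Package: spalos
Title: Spatial Regression Analysis of Healthcare Accessibility and Hospital Length of Stay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for small-area analysis of the relationship between spatial
    accessibility to healthcare services and hospital length of stay (LOS).
    Provides a synthetic areal-data generator with a two-level unit hierarchy
    and known ground truth, enhanced two-step floating catchment area (E2SFCA)
    accessibility indices, an age-standardized LOS indicator with variance
    inflation factor screening, ordinary least squares, maximum-likelihood
    spatial-lag (SAR) and geographically weighted regression (GWR) model
    fitting with adaptive Gaussian kernels and AICc bandwidth selection, and
    spatial diagnostics: global and local Moran's I (LISA cluster maps), a
    coordinate-permutation Monte-Carlo test for spatial non-stationarity of
    GWR coefficients, and model and scale comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
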