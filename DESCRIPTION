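Package: weightopt
Title: Optimal Weighting Parameters for Crystallographic Least-Squares
    Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calculates optimized a and b parameters of the six-parameter
    SHELXL-style weighting scheme w = q/[sigma^2(Fo^2) + (aP)^2 + bP + d +
    e*sin(theta)/lambda] for least-squares crystallographic refinement on
    F^2, by minimizing the variance of the weighted goodness of fit across
    ten Fc-ordered resolution-independent bins with an adaptive 9x9 grid
    search.  Reads SHELXL .fcf (LIST 4/8) and XD .fco structure-factor
    files plus .ins/.mas/.cif metadata, computes refinement statistics
    (R1, wR2, GooF, wGooF), and provides every-point normal probability
    plots of weighted residuals with an interquartile regression line as a
    normality diagnostic.  A synthetic-data generator with the same
    variance model supports fully offline testing and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
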