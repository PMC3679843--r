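Package: applidom
Title: k-Nearest-Neighbour Applicability Domain Assessment for QSAR Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to decide whether a QSAR model's prediction for a query
    molecule is reliable. Implements a three-stage k-nearest-neighbour
    applicability-domain (AD) procedure: per-training-sample distance
    thresholds derived from a Tukey upper fence on average k-neighbour
    distances, a decision rule counting how many training thresholds a query
    satisfies, and Monte Carlo optimization of the smoothing parameter k.
    Also provides the classical comparison AD methods (bounding box, PCA
    bounding box, convex hull, centroid-distance and classical kNN
    percentile thresholds) and density-based ADs (fixed, optimized, variable
    and adaptive Gaussian kernels, Epanechnikov kernel, nearest-neighbour
    density), plus reliability reporting with the predictive squared
    correlation coefficient and standardized prediction errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
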