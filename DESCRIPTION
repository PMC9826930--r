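Package: wormcast
Title: Forecasting C. elegans Lifespan Curves from Early Assay Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for predicting the remaining survival curve of a
    Caenorhabditis elegans lifespan assay from the live counts and
    worm-position images gathered over its first days. Provides a
    Weibull-based assay simulator with capture-gap distortions, a
    synthetic-domain image renderer (circles at worm centroids on a gray
    background), a bimodal sequence-regression network (CNN-LSTM image
    branch plus LSTM count branch) trained purely on simulated plates, a
    Monte-Carlo input-perturbation uncertainty estimator with
    plate-to-condition error propagation, a log-rank based halting
    criterion that flags when the prediction is reliable enough to stop
    the assay, and evaluation utilities including a Weibull curve-fit
    baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    minpack.lm,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
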