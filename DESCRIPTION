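Package: seqseg
Title: Sequential Bayesian Segmentation of Noisy Signals
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised detection of power (variance) changes in zero-mean
    noisy signals, aimed at event detection in passive acoustic monitoring
    records and other long time series. Implements a closed-form marginal
    posterior for a single variance changepoint, a recursive binary
    segmentation driver whose stopping rule is the Full Bayesian Significance
    Test (FBST) of variance equality with a block Metropolis-Hastings sampler
    for the e-value, the Palshikar peak-detection baseline (S1/S2/S3 spike
    functions), a piecewise-variance Gaussian signal simulator, WAV
    input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
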