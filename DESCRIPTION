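Package: nocidepth
Title: Depth and Threshold Estimation for C-Fiber Nociceptors from
    First-Spike Latencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the depth and heat-activation threshold of
    C-fiber nociceptor endings in skin from first-spike latencies recorded
    under ramped heat stimulation. Implements the quasi-static Henriques
    approximation of heat conduction into a semi-infinite solid, the
    classical depth-threshold intersection method with its four-outcome
    classification, a maximum-likelihood estimator that allows exponentially
    distributed delays between threshold crossing and the first spike,
    literature-based priors with a Gaussian-mixture approximation of the
    induced normalized-depth prior, and marginal-likelihood model selection
    that detects spontaneous (non-stimulus-driven) outlier first spikes.
    A ground-truth simulator of the stimulation protocol supports
    validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
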