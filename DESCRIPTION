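Package: meaosc
Title: Nested Oscillation and Burst Analysis for Multi-Electrode Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-electrode array (MEA) recordings of
    cultured neuronal networks. Converts per-well spike trains into a continuous
    population signal by kernel convolution, detects nested oscillation events in
    delta, theta and alpha bands with a dual-percentile amplitude-envelope method,
    parameterizes Welch power spectra into aperiodic (offset, exponent) and
    periodic (Gaussian peak) components, computes burst and network-burst metrics
    (interspike-interval and Poisson-surprise detectors, envelope network bursts,
    synchrony index), and models the emergence of oscillating wells across weeks
    with a weighted binomial-logit generalized estimating equation with
    exchangeable within-plate correlation. Includes a synthetic MEA data
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
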