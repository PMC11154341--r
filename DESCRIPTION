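Package: anticipatr
Title: Anticipatory Dynamics and Direction of Information Flow in Paired Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting anticipatory dynamics between two interacting
    agents from their movement trajectories. Implements time-lag mutual
    information on discretized position series, three directed
    information-flow detectors (bivariate Granger causality with
    information-criterion order selection, Liang's covariance-based
    information flow rate, and plug-in transfer entropy with finite history),
    a negative-group-delay simulator that generates anticipatory data with
    known information flow, and a synthetic two-agent tank trajectory
    generator with ground truth, assembled into an end-to-end classification
    pipeline distinguishing following, anticipatory and non-interacting pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
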