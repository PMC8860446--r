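Package: sniffcode
Title: Sniff-Aligned Analysis of Rate and Temporal Odor Codes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing odor-evoked single-unit activity aligned to
    the respiration (sniff) cycle. Implements inhalation-onset detection from
    a nasal pressure signal, trial alignment to the first odor inhalation,
    Gaussian-kernel spike-density estimation, activated-unit statistics and
    lifetime sparseness, pseudopopulation PCA trajectories with Euclidean
    distance time courses, sliding- and fixed-window linear (SVM) decoding of
    odor identity and intensity, peak-time and spike-synchrony statistics for
    temporal coding, and signal-detection (d-prime) analysis of
    two-alternative forced-choice lick behavior with optogenetic (LED)
    trial comparisons. A seed-controlled synthetic-data generator produces
    respiration traces, inhomogeneous-Poisson spike trains and behavioral
    sessions with known ground truth so that every stage of the pipeline can
    be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
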