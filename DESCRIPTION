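Package: circwear
Title: Circadian Phase Estimation and Desynchrony Analysis from Wearable Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates circadian phase from consumer wearable recordings by two
    independent routes: a sequential Bayesian cosinor model with AR(1) errors
    fitted to heart rate via an affine-invariant ensemble sampler (circadian
    rhythm in heart rate, CRHR), and a limit-cycle oscillator model of the
    human circadian pacemaker driven by an activity-derived light surrogate
    that predicts dim light melatonin onset (DLMO). Provides ingestion and
    5-minute binning of raw heart-rate/step streams, sleep and wear masking,
    circular alignment statistics comparing the two phase markers before and
    after a behavioural disruption date, and a synthetic cohort generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
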