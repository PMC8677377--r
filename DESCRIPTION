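Package: movewarp
Title: Comparison of Periodic Human Movements from Wearable Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares two periodic human-movement recordings (an expert's and a
    learner's) captured as wearable accelerometer time series. Recordings are
    reduced to acceleration-magnitude series, their cycle length is estimated by
    circular autocorrelation (Pearson iterations), the learner is phase-
    synchronized to the expert, both are smoothed and rescaled, and a randomly
    chosen movement cycle is compared by dynamic time warping: the warping path
    is regressed against the ideal line y = x, and equal periods, R-squared and
    the mean absolute line difference yield a similar/different verdict with
    localized feedback. Includes a synthetic periodic-signal generator and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
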