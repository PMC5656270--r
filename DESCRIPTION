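Package: chewmeter
Title: Chew Counting and Chewing-Rate Estimation from Jaw-Motion Sensor Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for objective quantification of chewing behavior from
    single-channel jaw-motion (e.g., piezoelectric strain) sensor recordings.
    Implements a percentile-threshold peak-detection chew counter on demeaned,
    low-pass-filtered signals, leave-one-out calibration of the threshold
    quantile, 5-second epoch segmentation with a 50 percent ground-truth
    labeling rule, a 38-dimensional time/frequency feature set, a small
    feed-forward neural-network intake classifier with leave-one-subject-out
    cross-validation, visit-level error statistics with confidence intervals
    and one-way ANOVA method comparison, and a seeded synthetic signal
    generator that emulates chewing bouts, rest periods, drift, noise, and
    motion/speech artifacts so the full pipeline is testable without real
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    nnet,
    optparse
Config/testthat/edition: 3
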