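Package: gesturekit
Title: Surface EMG Hand-Gesture Classification with Cuckoo Search Tuned
    Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for recognising basic hand gestures from two-channel
    surface electromyography (SEMG) envelope recordings. Provides a data
    model and file I/O for annotated multi-channel SEMG signals,
    sliding-window segmentation, the four classical time-domain features
    (mean absolute value, waveform length, Willison amplitude, slope sign
    change), a one-against-all soft-margin kernel support vector machine
    with quadratic, polynomial and radial basis kernels, and a Cuckoo
    Search metaheuristic with Levy-flight proposals that selects the
    kernel family and its parameters by maximising the 10-fold
    cross-validated classification rate, breaking ties by support-vector
    count. A seeded synthetic-signal generator emulates six-gesture,
    two-channel acquisition sessions so the full pipeline can be exercised
    and benchmarked without access to proprietary recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
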