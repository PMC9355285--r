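Package: lickometry
Title: Simulation, Detection and Microstructure Analysis for Multi-Cage
    Two-Bottle Lickometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico testbed and analysis toolkit for wireless
    multi-cage two-bottle lickometer systems. Generates synthetic mouse
    lick trains with bout structure and deterministic emulated pulse
    protocols, renders them as capacitive-style sensor traces, implements
    threshold/debounce lick detection for a 50 ms polling prototype and a
    16-channel multiplexed wireless acquisition at 60 ms frames, models
    lossy UDP-style transmission, scores detections against ground truth
    with tolerance-window precision/recall matching, runs a three-phase
    validation protocol over increasing cage counts, and computes drinking
    microstructure summaries (interlick intervals, bouts, lick frequency,
    two-bottle preference, time-binned counts) plus lick-count versus
    bottle-weight intake correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
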