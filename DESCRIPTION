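Package: chipbeat
Title: Beat Kinetics, Viability and Drug-Interaction Simulation for
    Multi-Tissue Organ-on-a-Chip Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies cardiac organoid contraction from time-lapse video by
    thresholded pixel-movement counting, detects beats and derives beat-rate
    and inter-beat-interval statistics with cessation flags, counts live and
    dead cells in two-channel LIVE/DEAD fluorescence images, and turns
    baseline/treatment beat metrics into pharmacological readouts including
    Hill dose-response fits and competitive-blockade analysis. A mechanistic
    simulator couples first-order hepatic drug clearance in a recirculating
    medium to a Gaddum/Schild competitive-antagonism beat-rate response, and
    a ground-truthed synthetic-data generator renders beating-organoid videos
    and stained-cell images for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    tiff,
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
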