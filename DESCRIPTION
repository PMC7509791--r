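Package: gazesal
Title: Individual Differences in Semantic Gaze Salience from Free-Viewing Fixations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Object-based scoring of free-viewing eye-tracking data and
    psychometric analysis of individual differences in semantic salience.
    Fixations are assigned to labelled scene objects via binary pixel masks
    (containment or a 0.5 degree radius), turned into per-observer cumulative
    dwell-time and first-fixation proportions, and analysed for split-half
    consistency across random image splits, cross-session validity, trial
    truncation effects, and greedy forward selection of stimulus subsets that
    preserve predictive validity. Includes a generative simulator of
    free-viewing gaze with known between-observer bias structure and
    Spearman-Brown based reliability calibration, so every analysis stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
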