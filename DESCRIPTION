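Package: edaprompt
Title: Simulated Wearable EDA Streams and Deviation-Triggered Experience Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for ambulatory studies that pair
    wrist-worn electrodermal activity (EDA) recording with smartphone
    experience-sampling prompts. Provides a synthetic 4 Hz EDA generator with
    known ground truth (tonic drift, phasic skin-conductance responses,
    arousal episodes, motion artifacts) and an export-style CSV dialect; a
    baseline-calibrated deviation-trigger engine with study-hour gating and a
    daily notification cap; a stratified random-interval prompt scheduler with
    reminders; the momentary survey instrument and its issue/answer/expire
    lifecycle; and feasibility analytics: engagement rates, one-way random
    ICC(1) sibling agreement with an aggregation gate, paired comparisons with
    Cohen's dz, endorsement tables, and USE subscale scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
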