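Package: ethoscore
Title: Keystroke-Based Behavioral Scoring, Visual Maps and Rater Agreement
Version: 0.1.0
Authors@R:
    person("Ethoscore", "Developers", email = "ethoscore@example.org",
           role = c("aut", "cre"))
Description: A scriptable toolkit for manual behavioral scoring of rodent
    tests such as the forced swim test (FST), novel object recognition (NOR)
    and the elevated plus maze (EPM). Timestamped keystroke logs are turned
    into validated bout timelines; timelines yield per-behavior totals,
    counts and latencies plus test-specific indices (immobility latency,
    percent time in open arms, discrimination and preference indices);
    timelines render as color-coded PNG "visual maps" for training and
    audit; two raters' scores are compared with per-measure Pearson
    correlation and timeline concordance (percent agreement, Cohen's
    kappa). A semi-Markov simulator generates synthetic sessions and noisy
    second-rater replicas so the whole pipeline is testable without animal
    data. Projects organize ethograms, subjects, groups and scored trials,
    and export RFC-4180 CSV result tables and per-animal map images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
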