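Package: phramp
Title: Fiber Photometry Ramps, Stimulation Plasticity and Approach Hazard Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-division-multiplexed fiber photometry and
    operant behavior: demultiplexing of a single-detector LED-multiplexed stream,
    isosbestic (405 nm) motion correction of dF/F traces, peri-event alignment of
    continuous signals and spike trains, shuffle-null statistics for approach ramps
    (max-min slope) and reward-click peaks, optogenetic stimulation dose-response,
    paired-pulse and linear-summation short-term-plasticity analysis with
    repeated-measures ANOVA, and hazard-rate analysis of trial-initiation latencies
    under pharmacological treatments. Includes a seeded synthetic-data generator
    (bleaching, shared motion artifacts, kernel transients, event-locked ramps,
    depressing evoked responses, Poisson spike trains, hazard-sampled latencies)
    with ground-truth access, so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    data.table,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
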