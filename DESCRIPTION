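Package: rotarena
Title: Rotating-Arena Place Avoidance and Circadian Actigraphy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for active allothetic place avoidance
    (Carousel maze) experiments and circadian locomotor actigraphy.
    Provides reference-frame transforms for rotating arenas, per-session
    trajectory measures (total distance, maximum time avoided, thigmotaxis,
    opposite-sector occupancy, post-shock angular speed), a shock-schedule
    reconstructor, a cohort statistics pipeline (per-session
    standardization, phase averaging, non-solver exclusion with matched
    removal, mixed ANOVA with generalized eta squared, Welch tests,
    polynomial trial contrasts, saccharin preference ratios), an actigraphy
    toolkit (double-plotted actograms, light-dark activity profiles,
    chi-square periodogram, free-running period, activity/rest ratios), and
    seeded simulators for arena trajectories, cohort tables and circadian
    count series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
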