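Package: skifuse
Title: Multi-Sensor Analysis of Roller-Ski Skating Sessions on Varying Terrain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested pipeline for analysing low- versus high-intensity
    roller-ski skating sessions on varying treadmill terrain from wearable and
    laboratory sensor streams. Covers the lap/segment protocol model, a
    synthetic multi-sensor session generator with ground truth, stream
    synchronisation and reduction to a 1 Hz master timeline, chest-IMU movement
    cycle detection and sub-technique classification (G2/G3/G4/other) with a
    support vector machine, wrist/ski inertial contact-time detection, pole and
    ski power partitioning from pole force and centre-of-mass velocity,
    terrain-dependent fluctuation and time-dependent change statistics, and
    normality-gated paired tests plus two-way repeated-measures ANOVA with
    Tukey post-hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    signal,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
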