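Package: whiskerVR
Title: Analysis of Closed-Loop Whisker Virtual-Reality Electrophysiology Sessions
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing extracellular recordings collected while a
    head-fixed mouse navigates a whisker-guided tactile virtual reality.
    Provides a seeded closed-loop session simulator (locomotion, rhythmic
    whisking, distance-triggered surface translations, contact events, and
    inhomogeneous-Poisson spike trains), whisker kinematics (angle,
    band-pass filtering, Menger curvature, cubic-window curvature
    derivatives, whisk phase, touch detection), event alignment and
    peristimulus time histograms, ANOVA/Tukey classification of transient
    and sustained neurons, gain/loss-of-contact modulation indices,
    habituation regression across stimulus repetitions, and time-resolved
    population decoding of surface location with cross-validation and
    resampling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
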