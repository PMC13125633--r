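Package: bowkin
Title: Bowing Kinematics and Haptic-Assisted Violin Training Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for teacher-learner violin bowing studies
    recorded with optical motion capture. Reads and cleans marker
    trajectories (Qualisys-style TSV and C3D), reconstructs ISB-convention
    upper-limb joint angles and the normalized bow-string contact
    coordinate, segments bow strokes, and derives seventeen spatial,
    temporal and spatiotemporal performance metrics including spectral
    arc-length smoothness (SPARC), vector-coding coordination variability
    and event-based circular synchronization. A statistics layer provides
    metric-rating Spearman screening with Bonferroni correction,
    two-way random-effects intraclass correlation, and participant-level
    cluster-bootstrap Group-by-Stage difference-in-differences contrasts.
    A synthetic-study module simulates the three training exercises,
    learner deviation models, viscous-elastic haptic guidance and expert
    panel ratings, so the full pipeline can be exercised end to end
    without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
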