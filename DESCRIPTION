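Package: beeflight
Title: Video Tracking, Flight Kinematics and Choice Statistics for Bee
    Wind-Tunnel Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing foraging flights of bumblebees filmed in
    wind tunnels and two-choice flight arenas. Implements the full video
    analysis chain (median background modelling, foreground segmentation
    with ellipse fitting, Kalman-filter data association, track pruning,
    stereo triangulation and wing-suppressed body-orientation refinement),
    per-flight kinematic summaries (ground and air speed, path sinuosity,
    body pitch angle, wingbeat frequency by FFT peak detection) with the
    standard inclusion filters, and exact small-sample nonparametric choice
    statistics (one-sample signed-rank and two-sample rank-sum tests by
    enumeration, exact binomial tests, one-way ANOVA with Tukey HSD and
    Kruskal-Wallis). A synthetic-data module generates ground-truth
    trajectories, rendered camera frames and choice-session tables so the
    whole pipeline can be exercised end-to-end against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
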