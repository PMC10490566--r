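Package: stancemat
Title: Plantar Pressure-Mat Analytics for Isometric Stance Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing plantar pressure-sensor matrices recorded
    during isometric stance (horse-stance / Mabu) training. Provides raw-frame
    input/output and threshold filtering, left/right foot segmentation,
    centre-of-pressure (COP) computation, moment-based foot geometry (toe-out
    angle, heel/forefoot load split, stance width), calibrated entry-stance
    validation, a real-time good/poor-posture monitor with lean-severity
    feedback and a break-detecting session state machine, level/group/
    leaderboard gamification mechanics, a parametric synthetic-stance
    simulator with ground-truth labels, and session analytics including a
    rank-sum (Mann-Whitney U) comparison of feedback conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
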