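Package: mousetrackr
Title: Mouse-Tracking Pipelines for Online Category-Competition Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for parsing, quality-controlling, and analyzing cursor
    trajectories from two-choice categorization experiments run on online
    survey platforms. Reads wide-format raw exports in which per-subject
    coordinate and timing streams are stored as character-separated strings,
    segments them into trials, undoes stimulus-order randomization, applies
    conservative quality-control flags (missing trajectories, non-standard
    pixel scaling, too-small browser windows), and computes trial-level
    category-competition measures: horizontal direction changes (x-flips),
    maximum horizontal deviation from the ideal trajectory, area between
    actual and ideal trajectories, peak cursor speed, and reaction time.
    Fits marginal generalized estimating equations (GEE) models with an
    exchangeable working correlation and robust sandwich inference to
    estimate stimulus-ambiguity effects, with optional browser and
    operating-system moderation. Includes a synthetic-cohort simulator
    (two-attractor cursor dynamics plus export-dialect serialization and
    injected data idiosyncrasies) so the full pipeline can be exercised and
    validated without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
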