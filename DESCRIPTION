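Package: vfgn
Title: Headless Simulator and Analysis Pipeline for the Virtual Four
    Goals Navigation Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the virtual Four Goals Navigation (vFGN) task, a
    human analog of the Morris water maze run in a circular arena with
    distal cues.  Provides the arena geometry and coordinate conventions,
    the reference-memory (RM) and delayed-matching-to-place (DMP) session
    schedules, parameterized synthetic navigator agents whose pointing
    accuracy and path directness improve with repeated goal exposure and
    degrade with memory noise, the four trajectory-level performance
    measures (pointing error, path efficiency, goal-quadrant preference,
    entrance count), and cohort-level statistics (one- and two-sample
    t tests, mixed group-by-block analysis of variance, age correlations)
    implemented from closed-form sums of squares.  Trajectories, session
    configurations and metric tables round-trip through plain-text
    CSV/JSON formats so the pipeline is fully reproducible from seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
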