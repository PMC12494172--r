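Package: signtrack
Title: Sign- and Goal-Tracking Gaze Phenotyping and Connectome-Based
    Predictive Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying sign- versus goal-tracking behavior from
    eye-tracking recordings of a food Pavlovian conditioning task, and for
    relating that phenotype to brain functional connectivity with
    connectome-based predictive modeling (CPM). Includes a velocity-threshold
    (I-VT) fixation classifier, area-of-interest gaze indices with the task's
    quality-control and trial-exclusion rules, per-participant sign-/goal-
    tracking regression coefficients and group assignment, adjusted adiposity
    association models, confound regression and motion-spike scrubbing of
    parcellated node timecourses, Fisher-z connectivity matrices, and a
    leave-one-out cross-validated CPM with partial Spearman edge selection,
    permutation inference, consensus networks and canonical-network degree
    summaries. A synthetic-study generator with known ground truth makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
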