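Package: msdaf
Title: Clinical Disease Activity Endpoints and Dual-Gated Survival Trees
    for Relapsing-Remitting Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing clinical disease activity after a treatment
    switch in relapsing-remitting multiple sclerosis. Derives time-to-event
    endpoints (qualifying relapse, sustained EDSS progression, and the combined
    clinical disease activity-free status) from longitudinal Kurtzke
    functional-system records, runs Kaplan-Meier, log-rank and Cox
    proportional-hazards analyses of baseline predictors, and fits a
    dual-gated survival classification and regression tree in which every
    split must pass both a Cox score test and a log-rank test at a
    configurable significance level with a minimum node size. Includes a
    seeded synthetic cohort generator with piecewise-exponential event
    processes so the full pipeline can be exercised and validated without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
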