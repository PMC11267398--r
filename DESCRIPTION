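Package: socresp
Title: Paired Intermittent-Flow Respirometry: Simulation, Metabolic
    Endpoints and Status-Dependent Mixed-Model Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates paired dominant-subordinate intermittent-flow
    respirometry experiments (measure/flush cycling, circadian modulation,
    exhaustive-chase recovery kinetics, chamber observation physics) with
    known ground truth, converts raw oxygen traces into quality-controlled
    oxygen-consumption series, computes seven metabolic endpoints (resting,
    routine and maximum MO2, aerobic scope, time to 50% aerobic-scope
    recovery, time to within 10% of routine, and excess post-exercise
    oxygen consumption), and fits the corresponding linear mixed models
    with Type-III tests, partial eta-squared effect sizes and
    Tukey-adjusted marginal-mean contrasts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    lmerTest,
    emmeans,
    car,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
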