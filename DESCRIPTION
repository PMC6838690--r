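Package: pmflex
Title: Dynamic Prospective-Memory Strategy Analysis for Difficulty-Ramped
    Dual Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for prospective-memory (PM)
    dual-task experiments in which the difficulty of an ongoing visual
    search task ramps up or down within a trial. Provides deterministic
    generators for the difficulty parameterization, distractor arrays and
    block/session/localizer designs; a synthetic-cohort generator with a
    latent proactive-control strategy trace; reaction-time cost baselines,
    per-probe PM cost and within-trial PM cost slope statistics; per-trial
    polynomial model selection with AICc and Akaike weights;
    participant-level bootstrap logistic regressions linking strategy
    shifts to PM accuracy; and a simplified multivariate decoding stage
    (one-vs-rest penalized logistic classifiers, leave-one-run-out cross
    validation, scrambled-label chance calibration) yielding per-trial PM
    intention evidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
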