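Package: uccea
Title: Markov Cohort Cost-Utility Model of Adalimumab Therapy in
    Ulcerative Colitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic cost-utility modelling for moderate-to-severe
    ulcerative colitis, comparing readily available adalimumab therapy with
    ongoing medical therapy in a chronically unwell state. Implements a
    time-inhomogeneous Markov cohort engine with tunnel-state expansion for
    residence-time-dependent response retention, discounted cost and QALY
    accounting with transition-charged death costs, incremental
    cost-effectiveness ratios at 5/10/15-year horizons, dose-escalation and
    de-escalation scenarios, one-way (tornado) and probabilistic sensitivity
    analyses with cost-effectiveness acceptability curves, a random-model
    generator and a per-patient microsimulation oracle for engine validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
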