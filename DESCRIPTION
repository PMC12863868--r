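Package: igwohealth
Title: Grey-Wolf-Optimized Random Forests for Pediatric Health Risk Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tunes random-forest classifiers for pediatric health-status
    prediction with an improved grey wolf optimizer (IGWO) that adds a
    dynamic inertia weight, elite opposition-based learning, and elite
    retention to the standard pack-hierarchy search. Ships the full
    supporting pipeline: a synthetic cohort generator emulating a
    multi-hospital pediatric examination dataset (24 mixed-type features,
    imbalanced binary health label, diagnostic subgroups, missing entries),
    chained-equations imputation, Tukey-fence winsorization, min-max
    scaling, one-hot encoding and stratified splitting, a cross-validated
    complexity-penalized fitness, exact and permutation-sampled Shapley
    attribution with pairwise interaction indices, and an experiment
    harness for ablations and baseline comparisons (particle swarm,
    random search, fixed-configuration forests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    e1071
Config/testthat/edition: 3
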