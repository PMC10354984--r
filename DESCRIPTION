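Package: methpanel
Title: Targeted CpG-Panel Differential Methylation Analysis with Synthetic Cohorts
Version: 0.1.0
Authors@R:
    person("PKG", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted Illumina EPIC-array CpG panels in
    two-group cohort studies, built around a seeded synthetic-data generator so
    that every stage is testable without access to protected cohort data.
    Provides sample and probe quality control, beta/M-value transforms,
    batch adjustment through principal components of array control probes,
    empirical-Bayes moderated per-CpG linear models with Benjamini-Hochberg
    false-discovery-rate control, Gaussian-kernel differentially methylated
    region detection with a Satterthwaite null, sex- and age-interaction and
    glucocorticoid-treatment contrasts, and a cross-validated Fisher-combined
    robustness procedure for methylation-outcome associations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
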