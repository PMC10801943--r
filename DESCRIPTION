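Package: coreniche
Title: Core Microbiome Inference via Occupancy Ranking and Neutral Models
Version: 0.1.0
Authors@R: person("Core", "Niche", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers the core microbiome from amplicon (ASV-level) count tables
    by ranking taxa on occupancy and replicate consistency under pooled or
    site-specific occupancy models, measuring each ranked prefix's contribution
    to Bray-Curtis beta-diversity structure, and stopping by a last-2-percent
    or elbow criterion. Fits the Sloan neutral community model to
    abundance-occupancy distributions and partitions taxa into host-selected,
    neutral and dispersal-limited classes. Includes the supporting
    pre-processing filters (lineage exclusion, prevalence-based contaminant
    flagging against negative controls, low-yield sample removal), alpha/beta
    diversity statistics with PERMANOVA, chi-squared/log-linear contingency
    analysis of questionnaire covariates, and a seeded synthetic-community
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    vegan,
    withr
Config/testthat/edition: 3
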