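Package: secdiff
Title: Differential Analysis of Cofractionation Mass Spectrometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and statistically compares protein assembly states from
    size-exclusion chromatography coupled to mass spectrometry (SEC-MS)
    cofractionation experiments with multiple conditions and replicates.
    Provides peptide-trace import, spline imputation, cyclic loess
    normalization and sibling-peptide filtering; coelution peak-group
    (feature) detection with target-decoy q-value estimation; global
    assembled-mass-fraction (AMF) and feature-specific mass-fraction (FMF)
    beta-regression likelihood-ratio tests; feature-level, global and
    complex-level differential intensity testing with order-statistic
    aggregation of peptide-level p-values; hypothesis-driven protein complex
    detection with molecular-weight filtering and redundancy collapsing; and
    a seeded synthetic-data generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
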