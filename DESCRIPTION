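Package: faersdispro
Title: Case/Non-Case Disproportionality Analysis for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection on
    FAERS-style spontaneous adverse-event report data, built around the
    case/non-case design used to screen cardiovascular toxicity of the
    BCR-ABL tyrosine-kinase inhibitors licensed for chronic myeloid
    leukemia. Provides readers and writers for FAERS-dialect delimited
    tables, free-text drug-name normalization to INN with ATC indexing,
    a report-inclusion funnel (seriousness filter, two-step
    deduplication, aberrant-date exclusion), narrow-scope SMQ case
    classification, crude and age/sex-adjusted reporting odds ratios
    with Wald confidence intervals and signal flagging, time-to-onset
    summaries, descriptive tables and forest plots, and a synthetic
    report generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
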