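Package: cohortql
Title: Temporal Query Language Engine for Cohort Search over Longitudinal Patient Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A time-aware cohort search engine for longitudinal clinical
    records. Implements a temporal query language (TQL) with Boolean and
    interval algebra (UNION, INTERSECT, INVERT, SEQUENCE with
    presence/absence windows, COUNT, FIRST MENTION, NO HISTORY OF,
    NEVER HAD, DIFF), executed over an in-memory datastore of per-patient
    objects with an inverted feature index for candidate prefiltering.
    Ingests a subset of the OMOP Common Data Model from CSV files, expands
    diagnosis and drug codes at load time through ICD parent-child and
    RxNorm-to-ATC knowledge graphs, and exports cohorts as JSON, CSV flat
    files, summary statistics, and per-patient timelines. Ships a seeded
    synthetic-cohort generator with planted, known-truth temporal
    trajectories for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
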