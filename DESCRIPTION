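Package: dianet
Title: Graph-Based Prediction of Fast and Slow Progression to Diabetes
    Complications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds heterogeneous comorbidity networks from longitudinal
    electronic-health-record tables (diagnosis events, demographics, clinical
    laboratory panels) for newly diagnosed type-2-diabetes patients, labels
    patients as fast or slow progressors to each of six complications by
    time-to-complication quartiles, prunes network nodes and edges by a
    two-proportion Z-test, and scores new patients with a product-form
    naive-Bayes risk of fast progression. Includes a synthetic EHR cohort
    generator with planted feature effects that provides ground-truth oracles
    for every pipeline stage, plus repeated-holdout ROC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
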