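Package: ddiconcord
Title: Concordance Analysis of Drug-Drug Interaction Resources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess agreement between drug information resources
    (DIRs) on drug-drug interactions (DDIs). Normalises and canonicalises
    heterogeneous DDI tables (drug name mapping, drug-class expansion,
    unordered-pair deduplication), quantifies listing agreement through
    Venn partitions, coverage rates and Jaccard indices, cross-tabulates
    severity and evidence ratings between resources, and annotates
    free-text clinical-management advice with multi-label categories using
    tf-idf sentence encoding, class-weighted linear support vector
    machines, leave-one-out ROC analysis and precision-constrained
    threshold selection. A synthetic-data generator with fully known
    ground truth (configurable three-set overlap structure, salt-name
    variants, class-level rows, rating distributions and template advice
    sentences) makes every pipeline stage testable without access to the
    licensed source compendia.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
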