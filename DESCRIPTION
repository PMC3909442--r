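Package: famagg
Title: Familial Aggregation of Breast Tumor Molecular Subtypes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing molecular subtype structure in familial
    breast cancer cohorts: nearest-centroid classification of expression
    profiles into the intrinsic subtypes (basal-like, HER2-enriched,
    luminal A, luminal B, normal-like), a permutation test for familial
    aggregation of subtypes with an exact-enumeration null as oracle,
    linear signature classifiers flagging BRCA1-like and BRCA2-like
    tumors, promoter methylation calling from MS-MLPA ratios, and
    hierarchical clustering of the most variant genes. Includes a
    synthetic cohort generator so every stage is testable without
    external data, and ships family-by-subtype tables as plain-text
    fixtures making the aggregation results reproducible offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
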