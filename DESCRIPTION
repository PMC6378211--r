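Package: ceRNAti
Title: Time-Course ceRNA Network Inference for Ischaemia-Reperfusion Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers lncRNA-miRNA-mRNA competing-endogenous-RNA (ceRNA)
    networks from short patient time-course expression data. Implements
    coefficient-of-variation screening with cross-patient intersection,
    weighted gene co-expression network analysis (soft-threshold power
    selection, topological overlap, module detection, module-trait
    association), short time-series model-profile clustering with
    permutation significance, ceRNA triplet assembly from typed regulatory
    pair sets, offline hypergeometric functional enrichment, and a seeded
    synthetic-data generator with planted modules, profiles and triplets
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
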