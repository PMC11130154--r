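Package: cafsubtypes
Title: Cancer-Associated Fibroblast Subtyping from Cytometry, Imaging,
    Single-Cell and Survival Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies and characterises cancer-associated fibroblast (CAF)
    subsets (CAF-S1 to CAF-S5) in solid tumours. Provides flow-cytometry
    preprocessing (viability/lineage gating, downsampling, geometric MFI),
    self-organizing-map clustering with automatic metacluster selection and
    ordinal marker-profile labelling, rule-based phenotyping of multiplex
    immunofluorescence cell tables, distance-to-tumour spatial statistics,
    marker-based single-cell RNA-seq filtering with rank-based differential
    expression, and survival stratification including maximally selected
    log-rank cutpoints. A synthetic-data module generates all input
    modalities with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    methods,
    class,
    cluster,
    mgcv,
    survival,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
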