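Package: mutscreen
Title: Mutation-Association Screening, Transcriptomic Signatures and
    Survival in Immune-Marker-High Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Screens somatic mutations for association with elevated
    expression of immune-checkpoint markers (PD1/PD-L1) via Mann-Whitney
    tests and fold changes, assembles frequency-ranked gene signatures,
    derives mutation-associated transcriptomic signatures scored as mean
    expression with median-split Cox survival comparison, and evaluates
    mutation co-occurrence (Fisher exact odds ratios) and purity-corrected
    partial Spearman correlations with immune-cell infiltrates. Includes a
    seeded synthetic multi-omic cohort generator with planted mutation
    effects, co-occurrence structure, proportional-hazards survival signal
    and purity-confounded infiltration links, so every stage of the
    pipeline is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
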