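Package: safetyome
Title: Evidence-Based Safety Target Panels from Human Genetics and Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds phenotype-anchored off-target safety panels from
    heterogeneous gene-trait evidence. Harmonizes per-source association
    tables under source-specific filters, maps free-text traits onto a
    two-level organ / preferred-term ontology with a cascaded
    exact-fuzzy-embedding matcher, scores targets by evidence breadth
    (record counts weighted by unique supporting sources, then z-scored,
    log-transformed and rescaled to 0-10), assembles organ-level and
    phenotype-level gene panels, prioritizes a core panel by tissue
    specificity (Tau) and cross-species conservation, and validates panels
    against an independent disease-gene resource by hypergeometric
    over-representation and label match rates. A deterministic synthetic
    world generator with planted ground truth supports end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tools,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
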