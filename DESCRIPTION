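Package: hdmp
Title: Disease-miRNA Prioritization by Weighted k Most Similar Neighbors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate disease-associated microRNAs from validated
    miRNA-disease association catalogs. Disease-disease similarity is computed
    from MeSH-style ontology DAGs under either a layer-based semantic
    contribution scheme or an information-content scheme, optionally fused
    with text-mining phenotype similarity. miRNA functional similarity is the
    best-match average similarity between the two miRNAs' disease groups.
    Candidates are scored by their weighted k most similar neighbors, with
    multiplicative weights for shared miRNA families (miFam-style) and
    genomic clusters (within 20 kb). Includes per-disease k-fold
    cross-validation and temporal hold-out evaluation with ROC/AUC,
    parameter sweeps, and deterministic synthetic-corpus generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
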