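Package: aliendist
Title: Harmonize and Integrate Native and Alien Species Distribution Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates heterogeneous sources of alien-species occurrence
    data (regional checklists and range maps) into a single standardized
    two-table dataset of native and alien distributions. Provides declarative
    per-source ingestion, translation-table standardization of Darwin Core
    invasion-status vocabulary, taxonomic name resolution against a pluggable
    taxonomy backbone (exact, synonym and fuzzy matching with homonym
    resolution), range-map-to-checklist spatial overlay, first-record date
    normalization, deterministic record merging with full provenance, and
    matched/unmatched term reporting. Ships a synthetic fixture generator
    with a ground-truth ledger so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
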