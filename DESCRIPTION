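Package: bioinventory
Title: Build a Biodata Resource Inventory from the Scientific Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling an inventory of biodata resources (online
    sources of structured biological data) from the titles and abstracts of
    life-sciences articles. Provides corpus retrieval against a pluggable
    literature API client, article classification and BIO-scheme named-entity
    decoding with per-mention confidence scores, URL extraction, candidate
    filtering, record deduplication and review flagging, application of
    manual-review decisions, enrichment with article metadata, URL liveness
    and web-archive status, IP and affiliation geolocation, funder-frequency
    summaries, registry overlap comparison, evaluation metrics for the
    classification and named-entity tasks, and a deterministic synthetic
    corpus generator with offline stand-ins for every network service.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
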