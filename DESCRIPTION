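Package: coldtrace
Title: Cold-Chain Compliance Auditing for RFID-Tracked Blood Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reconstructs per-product journeys of RFID-tagged red blood cell
    concentrates from tag event streams, splits each journey into storage,
    transport and transfusion phases, applies temperature data-quality and
    dataset inclusion rules, evaluates compliance with four intrahospital
    storage, transport and distribution guidelines, and classifies products
    with a decision tree. Includes a discrete-event cohort simulator with a
    first-order thermal-lag sensor model and configurable missingness modes
    (reading dropout, stop-box misuse, unregistered returns), emitting event
    streams together with ground-truth labels for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
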