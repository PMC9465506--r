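Package: declineCJS
Title: Decline Curves and Cormack-Jolly-Seber Persistence Models for
    Species Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Turns dated species-occurrence records into decade-binned
    locality detection histories, charts locality loss with cumulative
    decline curves, and estimates population persistence (Phi) and
    population detectability (p) with Cormack-Jolly-Seber models under
    constant, linear, quadratic or fully time-dependent structures
    compared by small-sample-corrected AIC (AICc).  A simulator of
    locality occupancy and detection dynamics supports validation and
    parameter-recovery studies without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
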