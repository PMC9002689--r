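Package: aaemetrics
Title: A Priori Performance Metrics for Activity-of-Daily-Living Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models activities-actions-events (AAE) decompositions of
    activities of daily living observed through smart-home binary sensors,
    and computes a priori recognition-performance metrics on them:
    participation counters, asymmetric sharing rates, weights, elementary
    contributions and distinguishabilities, all in exact rational
    arithmetic. Includes a top-down diagnostic analyzer that flags
    hard-to-separate activities and drills down to the responsible events,
    a synthetic decomposition generator and ground-truth-annotated
    event-stream simulator for validation studies, an embedded smart-flat
    case-study fixture, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
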