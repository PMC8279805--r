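Package: apneacost
Title: Decision-Analytic Cost Modelling of Diagnostic Pathways for
    Obstructive Sleep Apnea
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Expected-cost decision trees comparing four diagnostic
    strategies for suspected obstructive sleep apnea: in-laboratory
    polysomnography first, home Level II polysomnography first, and a
    limited-channel Level III home study followed by either modality.
    Provides an exact terminal-state enumeration engine, closed-form
    checks, pretest-probability sweeps with least-cost frontiers,
    crossover-probability and break-even cost solvers, one-way
    sensitivity tables, an event-level Monte Carlo cohort simulator used
    as an independent verification oracle, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
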