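Package: oma
Title: Options-Market Valuation and Simulation for Antibiotic Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Valuation and simulation toolkit for an options market for
    antibiotics: prices call options on antibiotics in clinical development
    at any phase using staged transition probabilities, derives drug-specific
    market payouts from an advance market commitment via novelty, class
    crowding and competitor efficacy, evaluates firm continue/abandon
    decisions by backward induction with an abandonment floor, and runs
    seeded Monte Carlo simulations of option-purchase portfolios. Ships the
    DiMasi per-class phase-transition probability table as a packaged
    fixture, reads scenario configurations from YAML or JSON, and exposes a
    command-line interface over the same functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
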