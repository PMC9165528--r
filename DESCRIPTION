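Package: nitrofoot
Title: Religion-Sensitive Food Nitrogen Footprint Accounting and Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for per-capita food nitrogen footprint accounting on
    food-balance-sheet style data. Computes crop cultivation nitrogen use
    efficiency (NUE) from nitrogen budgets, domestic and trade-considered
    virtual nitrogen factors (VNFs), and religion-weighted production and
    consumption nitrogen footprints. Includes diet and efficiency scenario
    construction (business-as-usual, +30% cultivation NUE, a
    religion-sensitive EAT-Lancet planetary health diet, and their
    combination), a from-scratch LSTM recurrent forecaster for projecting
    annual footprint series, and a synthetic food-balance-sheet world
    generator with closed-form ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
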