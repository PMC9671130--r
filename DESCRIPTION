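Package: nitrolag
Title: Dynamic Parcel-Level Nitrogen Loading with Groundwater Travel-Time Lags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates annual nitrogen loads delivered to estuaries from
    parcel-level sources whose inputs travel through groundwater with
    multi-year lags. Provides an annual time-step loading engine with a
    brute-force packet oracle, Monte Carlo buildout and source-control
    abatement scenarios, legacy (in-transit) nitrogen accounting,
    equilibrium diagnostics, watershed summary statistics, a synthetic
    multi-watershed parcel generator, and tidy CSV input/output with
    plotting helpers.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
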