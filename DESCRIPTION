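Package: ssncinvest
Title: Investment Case Modelling for Small and Sick Newborn Care Scale-Up
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-step investment-case pipeline for national scale-up of
    level-2 small and sick newborn care (SSNC): deterministic projection of
    neonatal deaths averted under intervention coverage scale-up, activity-based
    incremental costing of hospital newborn units under two scale-up scenarios,
    return-on-investment analysis with monetised life-years, and budget-impact
    metrics. Ships a fully worked Tanzania configuration and a generator of
    internally consistent synthetic country bundles for property testing.
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
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
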