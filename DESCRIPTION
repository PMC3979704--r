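Package: niptscreen
Title: Decision-Analytic Evaluation of Non-Invasive Prenatal Testing for
    Down's Syndrome Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Expected-value cohort model of the Down's syndrome prenatal
    screening pathway in a 10,000-pregnancy population, comparing the current
    combined/quadruple screening programme with non-invasive prenatal testing
    (NIPT) offered as contingent testing after a high-risk screening result or
    as first-line testing. Includes weekly fetal-loss survival dynamics, a
    configurable parameter bundle with uptake-scenario presets, a cost
    decomposition (screening, NIPT, invasive diagnosis, optional pregnancy
    outcomes), pooling of NIPT validity studies into merged sensitivity and
    specificity with Wilson score intervals, a scenario grid runner, and a
    seedable individual-level microsimulator used as a stochastic oracle for
    the deterministic engine.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
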