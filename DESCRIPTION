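Package: hearcea
Title: Cost-Effectiveness Analysis of Newborn Hearing Screening Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree cost-effectiveness analysis of first-line universal
    neonatal hearing screening strategies (portable automated auditory
    brainstem response versus otoacoustic emission) with brainstem evoked
    response audiometry confirmation. Provides micro-costing of screening
    modalities (apportioned salaries, annualized equipment, consumables,
    overheads), four-branch diagnostic cascade expectations under
    sensitivity/specificity or observed detection rates, undiscounted QALY
    and incremental cost-effectiveness ratio computation from health-system
    and societal perspectives, one-way sensitivity sweeps, and an
    individual-level Monte-Carlo cohort simulator that validates the
    deterministic model. Ships a reference configuration reproducing a
    published India 2019-20 costing scenario, including a discrepancy log of
    its internally inconsistent printed values.
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
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
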