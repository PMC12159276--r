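Package: pvsignal
Title: Disproportionality-Based Signal Detection for Spontaneous
    Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on
    spontaneous-report databases in the style of the FDA Adverse Event
    Reporting System (FAERS). Builds drug-event 2x2 contingency tables
    restricted to primary-suspect drugs, computes the reporting odds
    ratio (ROR) with Woolf confidence intervals, the proportional
    reporting ratio (PRR), the Pearson chi-squared statistic, and the
    Bayesian confidence propagation neural network (BCPNN) information
    component, and applies layered signal criteria (Evans thresholds,
    IC025 > 0 validation, and case-count/ROR floors) to rank drug-event
    pairs. Includes demographic and temporal report summaries, readers
    and writers for FAERS-style delimited tables, and a synthetic-data
    module that reconstructs report sets exactly matching a specified
    set of 2x2 margins or simulates reports with injected associations
    of known strength.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
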