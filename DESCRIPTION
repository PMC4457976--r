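Package: evcost
Title: Workload Equivalent-Value Costing of Primary Health Care Service Packages
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Normalizes heterogeneous primary-health-care services to
    standard-clinic-visit equivalents (EV), estimates the cost of one EV
    from facility expenditure and service-volume data, and derives
    program-level costs, per-capita costs, funding gaps, and repriced
    what-if scenarios. Ships the reference service catalog and
    stratum-level expenditure/workload data from a 2010 costing study of
    17 Beijing community health centers, plus a synthetic-panel generator
    with planted ground truth for end-to-end validation. All user-facing
    functions take data frames and return tibbles; fitted cost reports
    support tidy(), glance(), and autoplot().
License: MIT
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
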