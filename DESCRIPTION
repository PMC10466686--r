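Package: scorkit
Title: Harmonization and Cohort Summaries for Child Dental Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with visit-level child dental registry data
    recorded under three historical registration regimes (1972-1987,
    1988-1999, 2000-present). Provides era-aware readers and validators for
    delimited visit and person tables, a cleaning pipeline (duplicate
    removal, faulty-record filters, one-entry-per-age restriction) with an
    auditable report, harmonization of gingivitis, periodontitis and caries
    (DMF-S) registrations into era-comparable aggregate variables, and
    descriptive cohort summaries (entry statistics, period coverage,
    prevalence per 1000, visit-year distributions, denominator comparison).
    Includes a synthetic-registry generator with planted latent disease
    trajectories and injected faults so the full pipeline is testable
    without access to the restricted source registry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
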