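Package: swaft
Title: Smartwatch Activity Feedback Trial Analytics and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for wrist-worn accelerometry feedback interventions in
    inpatient stroke rehabilitation and for the feasibility analytics of the
    pilot trials that evaluate them. Converts tri-axial accelerometer traces
    into per-epoch activity scores and movement-based wear estimates on a
    fixed five-period daily schedule, implements the adaptive 5% goal rule
    and the four-bar progress display used by the feedback smartwatch,
    handles eligibility screening and concealed 1:1 randomisation, and
    computes recruitment, retention, completion, adherence and
    baseline-exceedance metrics. A synthetic cohort simulator with
    controllable effect sizes, wear gaps, weekend recording and dropout makes
    every step testable without device data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    hms,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
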