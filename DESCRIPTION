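Package: captree
Title: Decision-Analytic Model of Cap-Score-Guided Management of Unexplained Infertility
Version: 1.0.0
Authors@R:
    person("Model", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Closed-form evaluation of a decision tree comparing Cap-Score-guided
    timed intrauterine insemination (CS-TI) against the standard of care (SOC,
    three IUI cycles followed by three IVF-ICSI cycles) for couples with
    unexplained infertility. Provides the published parameter table with
    maternal-age-banded per-cycle pregnancy and live-birth probabilities,
    beta/truncated-normal distribution fitting for probabilistic sensitivity
    analysis, a patient-level cohort microsimulator used as a brute-force
    oracle, Monte Carlo probabilistic sensitivity analysis with percentile
    credibility intervals, one-way (tornado) sensitivity analysis, and a
    command-line interface that renders baseline, PSA, and tornado tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
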