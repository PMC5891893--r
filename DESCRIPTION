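Package: endocea
Title: Markov Cohort Cost-Effectiveness Model of Early Intervention for
    Dysmenorrhea and Endometriosis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A yearly-cycle Markov cohort model of dysmenorrhea and
    endometriosis in Japanese women aged 12 to 35, comparing early
    guideline-based medical intervention (oral contraceptives or progestin
    with regular gynecologic follow-up) against self-care. Implements
    exponential rate-probability conversion with odds-ratio hazard
    adjustment, calibration of unobserved progression parameters against
    national prevalence targets, payer-perspective cost-per-QALY (ICER) and
    societal cost-benefit (societal monetary value) accounting with
    discounting, one-way deterministic (tornado) sensitivity analysis, and
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves. Ships synthetic stand-ins for the external
    inputs (life table, female population counts, utility survey) so the
    whole pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
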