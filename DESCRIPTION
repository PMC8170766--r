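Package: bphcea
Title: Markov Cohort Cost-Utility Model for Moderate Benign Prostatic
    Hyperplasia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-analytic cost-utility model comparing long-term
    5-alpha-reductase-inhibitor pharmacotherapy (dutasteride) against
    immediate surgery (a transurethral resection / open prostatectomy mix)
    for moderate benign prostatic hyperplasia. Implements a seven-state
    annual-cycle Markov cohort model with decision-tree entry, an
    IPSS-based utility mapping with linear extrapolation of the drug
    response, differential discounting of costs and utilities, incremental
    cost-effectiveness ratios with cost-effectiveness-plane classification
    and willingness-to-pay verdicts, one-way deterministic sensitivity
    analysis with tornado ordering, a named scenario catalogue, and an
    individual-level microsimulation used to validate the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
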