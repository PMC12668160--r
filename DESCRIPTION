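Package: crcscreen
Title: Cost-Effectiveness Microsimulation of Colorectal Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov microsimulation of the adenoma-carcinoma natural history
    of colorectal cancer with a screening-policy overlay (colonoscopy,
    sigmoidoscopy, FIT, FOBT), cost and disability-adjusted life-year (DALY)
    accounting from a healthcare payer perspective, incremental
    cost-effectiveness analysis with efficiency-frontier and willingness-to-pay
    decision logic, stepwise simulated-annealing calibration of natural-history
    transition probabilities to incidence, adenoma-prevalence and
    stage-distribution targets, and deterministic, probabilistic and scenario
    sensitivity analyses. Ships a synthetic-fixture generator so the whole
    pipeline runs end to end without external registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
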