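Package: markovcea
Title: Markov Cohort Cost-Effectiveness Engine for Early Health Technology Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A generic discrete-time Markov cohort model for estimating the
    incremental quality-adjusted life years (QALYs), healthcare and societal
    costs of a health or care intervention against standard care. Ships a
    canonical three-state model (baseline health, deteriorated health, death)
    with age-dependent baseline mortality from life tables, rate/probability
    conversion, discounting with half-cycle correction, ICER and incremental
    net monetary benefit summaries, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, deterministic scenario and
    one-way tornado analysis, mapping of other HRQoL instrument scores to
    EQ-5D utilities, and a JSON/CSV parameter database with validated user
    overrides and a synthetic fixture generator. Includes a command-line
    front end for config-driven runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
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
RoxygenNote: 7.3.3
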