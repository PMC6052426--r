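Package: vtecea
Title: Cost-Effectiveness of Oral Anticoagulation for Venous Thromboembolism
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort state-transition model for the treatment and
    secondary prevention of venous thromboembolism (VTE) with a non-vitamin-K
    oral anticoagulant (edoxaban) versus warfarin, from a UK NHS perspective.
    The model tracks VTE recurrence, bleeding events (clinically relevant
    non-major bleeds, non-intracranial major bleeds, intracranial
    haemorrhage), and the long-term sequelae post-thrombotic syndrome,
    chronic thromboembolic pulmonary hypertension and post-ICH disability,
    over monthly cycles and a lifetime horizon. Provides discounted
    life-years, QALYs and category-split costs, incremental
    cost-effectiveness and net-monetary-benefit statistics, one-way
    deterministic (tornado) and probabilistic sensitivity analyses with
    cost-effectiveness acceptability curves, scenario analyses and
    index-event subgroup analyses, plus a synthetic general-population life
    table so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
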