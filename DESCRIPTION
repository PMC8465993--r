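Package: ecoclues
Title: Land-Use Change Simulation and Ecosystem-Service Importance Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A CLUE-S style land-use change modelling pipeline with ecosystem-service
    importance assessment. Provides a Markov-chain demand module, per-class stepwise
    logistic suitability models with ROC validation, an iterative competitive spatial
    allocator with elasticity and conversion rules, and Cohen's kappa map agreement.
    Four ecosystem-service calculators (water conservation by water balance, soil
    conservation by the universal soil loss equation, sandstorm-prevention capacity
    from a wind-erosion climate factor, and biodiversity habitat suitability from
    species occurrence envelopes) feed an ordinal importance grading, a maximum-value
    service overlay, and an urban-encroachment accounting table. A synthetic landscape
    generator with known logistic coefficients makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
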