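Package: lsffcost
Title: Cost Modelling for Large-Scale Fortification of Bouillon
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ingredient- and activity-based cost model for large-scale
    food fortification (LSFF) programs that use bouillon cubes as the
    delivery vehicle. Provides a micronutrient premix cost calculator
    (fortificant amounts from target levels, overages and activity levels;
    cost per kg of premix and per metric ton of fortified vehicle), a
    deterministic 10-year demand and cost projection engine with separate
    start-up and operational phases for industry and government, country
    scenario configurations in YAML/JSON with validation, packaged country
    fixtures, summary metrics (total program cost, cost per MT, cost per
    consumer reached, stakeholder cost shares), and one-at-a-time
    sensitivity sweeps over prices and program parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
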