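Package: mvpasim
Title: Markov Cohort Cost-Effectiveness Model for Adolescent Physical
    Activity Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An age- and sex-stratified Markov cohort simulation that converts
    a change in adolescent moderate-to-vigorous physical activity (MVPA) into
    lifetime risks of six chronic diseases (coronary heart disease, stroke,
    heart failure, type 2 diabetes, breast and colorectal cancer) and death,
    accumulates discounted, half-cycle-corrected costs and quality-adjusted
    life-years, and computes incremental cost-effectiveness (ICER, net
    monetary benefit, cost-effectiveness acceptability curves) with
    deterministic scenario and probabilistic sensitivity analysis. Parameter
    bundles are plain delimited tables plus a key-value scenario config; a
    fixtures module generates seeded synthetic epidemiology with the schema of
    the model's transition-parameter inputs so the whole model runs and tests
    offline.
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
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
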