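Package: caffscore
Title: Caffeine Consumption Phenotyping and Two-SNP Genetic Instrument Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building a refined caffeine-consumption phenotype from
    longitudinal beverage questionnaire data (coffee, tea and cola, with
    decaffeinated counterparts), constructing a two-SNP allelic score from the
    CYP1A1/CYP1A2 variant rs2472297 and the AHR variant rs6968865, and running
    the additive genetic association and instrument-validation analyses used in
    Mendelian randomization: per-time-point linear regressions, variance
    explained, within- and between-locus non-additivity tests, confounder
    balance checks and decaffeinated-drink negative controls. Includes a
    synthetic cohort generator calibrated to published summary tables so that
    the whole pipeline is testable without managed-access cohort data, plus a
    command-line interface and table renderers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    withr
Config/testthat/edition: 3
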