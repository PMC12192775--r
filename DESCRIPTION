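Package: fcmonitor
Title: Preharvest Monitoring of False Codling Moth Fruit Infestation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing and evaluating preharvest monitoring of
    false codling moth (Thaumatotibia leucotreta) infestation in citrus
    orchards. Simulates orchard-scale weekly fruit-drop censuses with
    configurable spatial aggregation, computes the infested-fruit-per-tree-
    per-week metric and its action-threshold exceedance, compares the
    five-data-tree protocol against whole-orchard sanitation censuses,
    determines fruit sample sizes by the Watson finite-population formula
    and by Monte Carlo resampling of sampling coverage, and tests the
    spatial dispersion (Poisson versus negative binomial) and time trend of
    per-lot infested counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
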