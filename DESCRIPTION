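Package: fortisim
Title: Simulation of Large-Scale Food Fortification Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models how large-scale food fortification shifts population
    micronutrient intake distributions and changes the prevalence of
    inadequate and excess intakes under six policy scenarios, and estimates
    what each scenario costs.  Usual-intake distributions are parametric
    (log-normal or gamma); fortification adds a mean shift that preserves
    the distribution's shape; prevalence of inadequacy is computed with the
    probability approach (integrating the requirement-exceedance risk curve
    over the intake density) and excess intake as exceedance of the
    tolerable upper level.  Includes a seeded synthetic-data generator that
    emulates the structure of global dietary and fortification-programme
    databases, a six-scenario pipeline with person-nutrient accounting, a
    bottom-up cost model (premix, industry, government, with capital
    annualisation), and three sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
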