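Package: seadose
Title: Radiological Dose and Heavy-Metal Intake Assessment from Seafood
    Consumption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing public exposure from the dietary intake of
    marine fish: quantification of naturally occurring radionuclides (Ra-226,
    Th-232, K-40) from HPGe gamma-spectrometry peak data under secular
    equilibrium, with efficiency-curve fitting, quadrature uncertainty budgets
    and Currie minimum detectable activity; per-capita daily radionuclide
    intake, committed annual effective dose and lifetime cancer risk from
    consumption parameters and ingestion dose/risk coefficients; estimated
    daily intake of heavy metals screened against tolerable daily intakes;
    one-way ANOVA with Tukey HSD comparisons across sampling locations; and a
    seeded synthetic-data generator mirroring a three-location, three-replicate
    fish and seawater survey design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
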