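Package: saltfort
Title: Simulating Multiple-Micronutrient Fortification of Salt
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling the contribution of zinc and folic acid
    fortification of iodized salt to population micronutrient intake.
    Estimates usual-intake distributions from single 24-hour recalls using
    externally imputed within-person variance (shrinkage on the log scale),
    builds discretionary-salt scenarios from total salt or the WHO 5 g/d
    recommendation, simulates per-person nutrient delivery from fortified
    salt, reports prevalence of inadequate (below the estimated average
    requirement) and excessive (above the tolerable upper intake level)
    intake by demographic stratum, and selects fortificant addition rates
    that maximize the reduction in inadequacy subject to an excess-intake
    constraint. Includes a synthetic survey generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
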