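Package: flinchfit
Title: Dose-Response Fitting and Isobolographic Synergy Analysis for the
    Rat Formalin Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for preclinical opioid/monoamine-reuptake-inhibitor
    combination studies in the rat formalin model: per-animal flinch-count
    scoring over the phase-2A window, vehicle-normalized percent inhibition,
    constrained variable-slope sigmoid ED50 estimation with asymptotic
    confidence intervals, fixed-dose CI-shift tests and fixed-ratio
    isobolographic synergy evaluation under Loewe additivity, ex vivo
    transporter occupancy from radioligand binding initial rates, and
    in vitro transporter selectivity and unbound-concentration arithmetic.
    Includes a synthetic-data generator with known ground truth so every
    analysis stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
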