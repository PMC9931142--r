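Package: otxinduction
Title: Steady-State Model of Contact-Area-Dependent Neural Induction in the
    Ascidian Embryo
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a steady-state mathematical model of neural induction
    in the 32-cell ascidian embryo, in which the fractions of a cell's surface
    in contact with FGF-expressing mesendoderm and ephrin-expressing ectoderm
    determine ERK activation through a Ras-GTPase (SOS/p120RasGAP) cycle, and
    ERK in turn drives bimodal ON/OFF expression of the neural marker gene Otx
    via an Ets1/2 activator and an ERF2 repressor operating near zero-order
    ultrasensitivity. Provides the full perturbation-scenario registry
    (dnFGFR, Eph3dC, RGdGAP, NVP, U0126, ERF2 morpholino), linear calibration
    of model outputs to dpERK immunofluorescence and Otx smFISH readouts with
    uncertainty propagation, Hill-coefficient estimation by nonlinear curve
    fitting and by the EC10/EC90 potency formula, one-at-a-time and random
    parameter sensitivity analyses, and a seeded synthetic-data generator for
    per-cell geometry and noisy readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
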