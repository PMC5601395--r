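Package: atheroQSP
Title: Hybrid Simulation of Early Atherosclerotic Plaque Growth Under
    Statin Therapy and Imperfect Adherence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative systems pharmacology simulator coupling a
    mechanistic model of early atherosclerotic plaque growth (Poiseuille
    hemodynamics, Kedem-Katchalsky transendothelial LDL transport, and a
    well-mixed arterial-wall inflammation cascade of monocytes, macrophages
    and foam cells) to compartmental simvastatin pharmacokinetics, an
    inhibitory indirect-response model of circulating LDL, daily dosing as
    discrete events, and a two-state Markov chain of medication adherence.
    Supports single-patient scenarios, scenario comparison (control versus
    treated versus imperfectly adherent), virtual-population variability
    studies, calibration of the control growth rate, and CSV export, with a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
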