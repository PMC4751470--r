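Package: kirblock
Title: Kinetic Modelling of Voltage- and Flux-Dependent Block of Inward
    Rectifier Potassium Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Continuous-time Markov models of Kir2.1-like channel pore block
    by intracellular Mg2+ and spermine, with voltage-dependent (Woodhull)
    and flux-coupled rate laws and blocker punch-through. Generates
    synthetic excised-patch voltage-clamp experiments (step families and
    two-pulse protocols, GHK open-channel currents, additive recording
    noise) and provides the analysis pipeline used on such recordings:
    exponential relaxation fits of block decays and slow unblocking tails,
    Hill fits of relative current giving apparent Kd per voltage, Kd-voltage
    curves with inward-rectification indices and voltage shifts, rate-
    versus-concentration and rate-versus-voltage (Woodhull) regressions,
    double-mutant-cycle coupling coefficients, and two-blocker synergy
    analysis against independence and additivity null models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
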