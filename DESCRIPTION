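Package: seroterm
Title: Kinetic Model of Serotonin Synthesis, Release, and Reuptake in a
    Serotonergic Nerve Terminal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic kinetic model of a single serotonergic nerve
    terminal: tryptophan uptake and pooling, tetrahydrobiopterin-dependent
    hydroxylation by tryptophan hydroxylase (with weak substrate inhibition),
    decarboxylation, vesicular packaging with leak, firing-driven release,
    reuptake by the serotonin transporter, catabolism to 5-HIAA, and
    5-HT1B autoreceptor feedback on synthesis and release.  Provides
    calibration of the under-determined constants to the published baseline
    steady state, stiff integration with discontinuous drivers (firing
    pulses, SSRI dosing, meal-driven serum tryptophan), steady-state
    solving by damped Newton iteration cross-checked against long
    integration, and scripted in-silico experiments (SERT-fraction sweep,
    stimulation pulses, meals, autoreceptor homeostasis, SSRI and 5-HT1A
    agonist dosing) with CSV/JSON reporting and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
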