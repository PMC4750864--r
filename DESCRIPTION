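Package: apaptox
Title: Physiologically Based Pharmacokinetic Modelling of Acetaminophen
    Hepatotoxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A whole-body, 14-compartment physiologically based
    pharmacokinetic (PBPK) model of acetaminophen (APAP) disposition in an
    average 70 kg adult, coupled to a hepatic toxicity sub-model tracking
    N-acetyl-p-benzoquinone imine (NAPQI) formation and glutathione (GSH)
    depletion. Hepatic clearance uses three saturable Michaelis-Menten
    pathways (glucuronidation, sulfation, CYP-mediated oxidation) and renal
    elimination uses a fixed extraction ratio. Time-dependent lifestyle
    scenarios (chronic APAP intake, binge alcohol consumption,
    fasting/malnutrition, and their chronic+alcohol combination) modulate
    pathway capacities and GSH regeneration. Includes multi-dose regimen
    simulation with event-based bolus dosing, toxicity metrics against the
    30%-of-normal GSH injury threshold, threshold searches, baseline GSH
    calibration, configuration file I/O, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
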