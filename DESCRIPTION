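Package: ssriload
Title: One-Compartment Pharmacokinetic Simulation and Fluoxetine-Matched
    Dose Titration for Selective Serotonin Reuptake Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates plasma concentration time courses of selective
    serotonin reuptake inhibitors (SSRIs) under arbitrary multi-dose
    schedules using a one-compartment model with first-order absorption
    and either first-order or Michaelis-Menten (saturable) elimination.
    Calibrates per-drug kinetic constants from published single-dose
    observables (Cmax, Tmax, half-life, volume of distribution), solves
    escalating 30-day dose regimens whose daily mean concentrations track
    the slow loading profile of fluoxetine 40 mg once daily, and provides
    a Pearson correlation stage relating SSRI half-life (and the time to
    90% of steady-state accumulation) to the relative risk of
    suicide-related events. Includes seeded synthetic-data generators for
    honest round-trip testing of every stage.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
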