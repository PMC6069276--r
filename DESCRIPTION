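Package: fluopbpk
Title: Pediatric Fluoride Pharmacokinetic Modelling and Reverse Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Physiologically-based pharmacokinetic (PBPK) modelling of
    multi-source fluoride exposure in 4- and 8-year-old children. Provides a
    flow-limited compartmental model with continuous hepatic infusion dosing,
    age-scaled physiology and clearances, calibration against published child
    urinary-excretion studies, reverse dosimetry turning spot-urine fluoride
    biomonitoring concentrations into absorbed daily doses, aggregate exposure
    assessment with source-specific bioavailability, and local parameter
    sensitivity analysis via normalized finite-difference indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
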