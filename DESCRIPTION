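Package: stepwedge
Title: Step-Wedge Phantom Quality Assurance for Helical Tomotherapy
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Filmless machine quality assurance for helical tomotherapy from
    on-board megavoltage CT (MVCT) detector signals acquired while an aluminum
    step-wedge phantom traverses the static slit beam. Fits a 19-parameter
    schematic (piecewise-linear) model to the detector time profile to derive
    couch speed and its uniformity, longitudinal field width and the transverse
    laser offset; fits modified-Gaussian curves to transverse detector profiles
    to locate the detector center, the sagittal laser and the radiation beam
    center; reconstructs a percentage depth dose from the step-level signals
    and checks beam energy consistency through the D20/D10 ratio; and registers
    interrupted/resumed deliveries to measure field-abutment mismatch. Includes
    a detector-acquisition simulator with known ground truth, an open CSV+JSON
    acquisition format, tolerance-flagged QA reports and a JSON-lines trend
    ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
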