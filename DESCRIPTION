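Package: phafed
Title: Adiabatic Constant-pH Lambda Dynamics on Model Titratable Compounds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale simulator and analysis toolkit for constant-pH
    lambda dynamics with adiabatic free energy dynamics acceleration of the
    titration coordinates. Titratable model compounds with analytically
    known pKa are propagated with per-coordinate Nose-Hoover chain
    thermostats at a high fictitious lambda temperature, a SHAKE-like
    charge-neutrality constraint with titratable buffer particles,
    multisite histidine tautomers under a hyperbolic-tangent restraint, and
    optional driven adiabatic dynamics of a conformational gate coordinate.
    The analysis stack covers frame classification, temper-reweighting of
    deprotonation statistics, free-energy profiles, generalized
    Henderson-Hasselbalch and coupled two-site titration fits, and pKa
    prediction error metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
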