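Package: oxishelf
Title: Shelf-Life Kinetics and FTIR Chemometrics for Lipid Oxidation in
    Stored Foods
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for accelerated shelf-life studies of stored foods based
    on lipid-oxidation markers and mid-infrared spectroscopy. Implements the
    assay arithmetic for moisture content, peroxide value (PV) and
    thiobarbituric acid reactive substances (TBARS); zero- and first-order
    oxidation kinetics with Arrhenius temperature dependence and closed-form
    shelf-life prediction; standard normal variate (SNV) and Savitzky-Golay
    derivative preprocessing for ATR-FTIR spectra; NIPALS partial least
    squares (PLS1) regression with leave-one-out cross-validation,
    variable-importance-in-projection (VIP) band selection and principal
    component analysis; and a synthetic-data generator that emulates a
    two-process, three-temperature accelerated storage design so the whole
    pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
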