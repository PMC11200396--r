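Package: isobolr
Title: Isobolographic Analysis of Two-Drug Cytoprotection in Cell-Based
    Oxygen-Glucose Deprivation Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying pharmacological interaction between two
    drugs from plate-based cytoprotection assays. Converts raw optical-density
    or fluorescence plate readings into viability, lethality, cytoprotection,
    LDH-cytotoxicity and percent-of-control endpoints; fits sigmoidal
    concentration-response models with probit or logit links and estimates
    effective concentrations (EC50, EC90, general ECp) with delta-method
    standard errors; constructs fixed-ratio (ray) mixture designs from
    monotherapy EC50s and geometric dilution series; and performs Loewe
    isobolographic analysis: theoretical additive EC50, additivity and
    interaction indices, Welch's t comparison of theoretical versus
    experimental mixture potency, and a synergy/additivity/antagonism call.
    A synthetic plate-experiment generator with a controllable Loewe
    interaction parameter supports validation and power studies without
    wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
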