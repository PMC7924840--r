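Package: skinsim
Title: Transdermal Drug Disposition with a Multilayer Skin Barrier Model
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates transdermal drug disposition using a resistance-in-series
    model of the skin barrier (stratum corneum, viable epidermis, dermis) with
    QSPR-derived layer partition coefficients and diffusivities. Predicts
    steady-state intra-skin concentrations in healthy and lesioned skin
    (stratum corneum removed), drives a reduced lumped-compartment systemic
    pharmacokinetic model from a depleting patch depot, and provides
    noncompartmental analysis (Cmax, tmax, AUC, AUMC, MRT, Vdss) together with
    fold-error model-validation statistics (AFE, AAFE, GMFE) and the ratio
    paired t-test. Ships parameter fixtures for two topical opioid analgesics
    (oxycodone and buprenorphine) and a seedable synthetic observed-profile
    generator for testing the validation machinery.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
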