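Package: cvdmicrosim
Title: Discrete-Time Microsimulation of Cardiovascular Disease Prevention
    Policies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time dynamic stochastic microsimulation of primary
    prevention of cardiovascular disease in a synthetic adult population with
    socioeconomic structure. Builds close-to-reality synthetic populations
    with deprivation gradients in risk-factor distributions and continuing
    secular trends; converts five-year-lagged exposures into first-ever
    coronary heart disease and stroke incidence through a multiplicative
    relative-risk model with competing-risk mortality; simulates universal
    and deprivation-concentrated risk-score-based screening, a structural
    population-wide diet and smoking intervention, and their combination;
    quantifies uncertainty with a second-order Monte Carlo design using
    common random numbers across scenarios; and summarises effectiveness and
    equity with cases and deaths prevented or postponed and regression-based
    absolute and relative equity slope indices.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
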