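Package: fgrapedbn
Title: Grape Berry Maturity Prediction by Coupling a Fuzzy Expert System
    with a Dynamic Bayesian Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-support modelling of grape berry ripening. Predicts
    weekly sugar and total-acidity concentrations of maturing berries from
    weather series by coupling a Mamdani-style fuzzy expert system (FGRAPE),
    which encodes winegrower knowledge as linguistic rules over daily
    climate, with a discrete first-order dynamic Bayesian network whose
    Dirichlet-smoothed conditional probability tables are learnt from weekly
    measurements and then enriched with simulated fuzzy-model transitions
    (FGRAPEDBN). Includes a Gaussian-process dynamic regression baseline,
    a seeded synthetic weather and kinetics generator, and a 10-fold
    cross-validation protocol with RMSE/R-squared reporting against
    oenological error thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
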