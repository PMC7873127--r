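Package: evoseize
Title: Evolutionary Hyper-Feature Search for Patient-Specific EEG Seizure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-specific seizure prediction from scalp EEG by evolutionary
    feature construction. A genetic algorithm evolves sets of five
    "hyper-features" (windowed, operator-aggregated spectral and amplitude EEG
    features placed on a pre-seizure timeline), each candidate being scored by
    a class-weighted logistic-regression classifier whose output is
    regularized with the Firing Power method before alarms are raised.
    Includes a synthetic scalp-EEG generator with plantable pre-ictal
    band-power signatures, EDF and CSV input, surrogate-based statistical
    validation (seizure-time shifting, one-tailed t-test, binomial count
    test), and an interpretability ("phenotype") study of the evolved gene
    values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    zoo,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
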