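Package: vo2kinetics
Title: Modelling of Oxygen Uptake On- and Off-Transient Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing pulmonary oxygen uptake (VO2) kinetics
    from breath-by-breath gas-exchange data, during both exercise
    (on-transient) and recovery (off-transient) periods. Provides
    preprocessing of raw breath series (errant-breath exclusion, 1-s
    interpolation, transition ensemble averaging, smoothing), unconstrained
    nonlinear least-squares fitting of mono- and bi-exponential transient
    models with and without time delays, nested-model F-test comparison and
    standard-error-of-regression based model selection, residual-bootstrap
    parameter uncertainty, paired on/off symmetry statistics (paired t-tests,
    Cohen's d, Hochberg step-up correction, Pearson correlation), and a
    synthetic-data generator producing noise-free and Gaussian-noise
    validation datasets as well as realistic irregular breath series.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
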