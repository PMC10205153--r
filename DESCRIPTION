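Package: erpbf
Title: Sequential Bayes Factor Analysis of Single-Trial ERP Amplitudes
Version: 0.1.0
Authors@R: person("ERP", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for dissociating contextual constraint (cloze entropy) from
    word predictability (cloze probability) in single-trial event-related
    potential (ERP) amplitudes. Builds cloze-based predictors (Laplace-smoothed
    log2 cloze probability, response entropy in bits), extracts N400/PNP/P600
    window amplitudes from segmented EEG epochs with peak-to-peak and
    voltage-step artifact rejection, fits hierarchical Bayesian linear mixed
    models with truncated effect priors by Gibbs sampling, computes Bayes
    factors by bridge sampling with prior-sensitivity sweeps and a
    Savage-Dickey cross-check, implements a sequential Bayes factor stopping
    rule and simulation-based design analysis, and analyses stop-signal
    sessions (SSRT by the integration method). A synthetic-data generator
    produces every input the pipeline consumes, with full seed control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
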