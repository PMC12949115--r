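Package: mepcov
Title: Trial-Level Covariation of Motor Evoked Potentials in Homologous Muscles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing trial-level covariation between motor evoked
    potential (MEP) amplitudes elicited in homologous forearm muscles by
    dual-site transcranial magnetic stimulation. Provides an S4 container for
    epoched bilateral surface EMG recordings, extraction of MEP peak-to-peak
    amplitude, MEP area and pre-stimulus r.m.s. background EMG, per-participant
    Spearman correlations with two covariate-adjusted (semi-partial) variants
    (Yeo-Johnson transformation with linear-model residuals, and cumulative-
    logit ordinal regression on ranks with probability-scale residuals),
    sample-level sign-based inference (exact binomial point probabilities,
    beta-binomial Bayesian sign tests, bootstrap confidence intervals, kernel
    density summaries), and a calibrated synthetic-data generator with
    ground-truth bookkeeping for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    yaml,
    jsonlite,
    signal,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
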