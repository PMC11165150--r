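Package: pvtfatigue
Title: Microlapse and Gamma-Power Models of Vigilance Decrement on the
    Psychomotor Vigilance Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forward simulation and fitting of production-cycle models of the
    10-minute Psychomotor Vigilance Test (PVT). Production utilities are
    degraded by accumulating microlapses and time-on-task (the computational
    model of fatigue) or moderated by a motivation parameter derived from
    frontal high-gamma (70-80 Hz) EEG power, either binned or per trial.
    Includes per-subject simulated-likelihood estimation via differential
    evolution MCMC with AIC model comparison, the accompanying behavioral
    analyses (response classification, time binning, inverse RT, quintile
    decrement tables with chi-square, lagged cross-correlation with
    bootstrap), a Welch spectral pipeline for per-trial band power, and
    synthetic-data generators for sessions, gamma series and EEG epochs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
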