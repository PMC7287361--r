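Package: dyadsync
Title: Dyadic Physiological Synchrony and Observational Threat Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for demonstrator-observer
    experiments on observational threat learning. Generates synthetic dyadic
    phasic electrodermal activity with a tunable demonstrator-to-observer
    coupling, scores event-related skin conductance responses, quantifies
    interpersonal synchrony by cross-recurrence quantification analysis
    (time-delay embedding, recurrence-rate calibration, determinism,
    laminarity, maximum line and relative entropy), reduces the synchrony
    metrics to a principal component, and tests whether synchrony predicts
    conditioned-response differentiation with trial-level mixed-effects
    models and a pseudo-dyad permutation null.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
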