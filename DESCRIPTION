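Package: cholattn
Title: Cholinergic Modulation of Attentional Spike-Train Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for extracellular spike-train recordings from
    covert spatial-attention tasks with iontophoretic drug application.
    Quantifies attentional modulation with ideal-observer AUROC and Cohen's d,
    screens cells with factorial ANOVA, fits the negative-binomial
    (gamma-gain Poisson) count model to estimate trial-to-trial gain variance,
    computes drug and attention modulation indices, subdivides cell classes by
    Gaussian-mixture clustering with AIC/BIC selection and a calibrated
    Hartigan dip test of waveform-width bimodality, and summarizes behavioral
    performance (hit rate, correct rejections, d-prime, session-normalized
    reaction times). A synthetic-data module simulates the task structure and
    gamma-renewal spiking with known ground truth so every stage is testable
    without recorded data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    car,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
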