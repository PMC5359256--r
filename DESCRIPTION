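Package: stngpe
Title: Spiking Network Model of the Subthalamo-Pallidal Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the recurrent circuit between the subthalamic nucleus
    (STN) and the external globus pallidus (GPe) with conductance-based STN
    neurons, leaky integrate-and-fire GPe neurons, short-term synaptic
    depression and facilitation, and stochastic multi-contact GABAergic
    release. Provides the spike-train analysis used to characterise
    parkinsonian 8-15 Hz burst oscillations: shuffle-compensated power and
    cross spectra with confidence levels, oscillatory-cell classification,
    Poisson-surprise burst detection, and population summaries. Includes
    scripted experiments for the normal and parkinsonian network states,
    conductance sweeps, and cortical-input stimulation protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    generics,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    yaml,
    withr
Config/testthat/edition: 3
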