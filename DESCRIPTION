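Package: ca1stp
Title: Short-Term Plasticity and CA1 Spiking Output Under Elevated Release
    Probability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven implementation of the three-state resource model of
    short-term synaptic plasticity (Tsodyks-Markram) with facilitating release
    probability, applied to CA3->CA1 Schaffer-collateral transmission. Provides
    closed-form inter-spike propagation of synapse state, EPSC train amplitude
    prediction under voltage clamp, a reduced conductance-based
    integrate-and-fire CA1 surrogate neuron, lognormal synaptic weight
    sampling, a theta-modulated generator of naturalistic CA3 place-cell spike
    trains, least-squares estimation of synapse parameters from normalized
    EPSC amplitude curves, sigmoid fitting of spike-probability gain curves,
    and spike-train statistics (ISI coefficient of variation, instantaneous
    frequency distributions, theta/gamma band probabilities). Includes
    orchestrated, seeded experiments contrasting a control condition with an
    increased release-probability condition, as observed after acute
    amyloid-beta elevation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
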