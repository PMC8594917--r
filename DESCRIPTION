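Package: synstdp
Title: Release-Probability Heterogeneity, Short-Term Dynamics and
    Spike-Timing-Dependent Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the width of the presynaptic
    release-probability distribution shapes the expression of
    spike-timing-dependent plasticity (STDP) at hippocampal
    Schaffer-collateral synapses.  Implements the Tsodyks-Pawelzik-Markram
    model of short-term synaptic dynamics coupled to leaky
    integrate-and-fire neurons with a soft-bounded additive STDP rule;
    maximum-likelihood gamma fitting (free and mean-constrained) of
    FM1-43 readily-releasable-pool signals used to model release
    probability; in-silico pairing and Poisson-train plasticity
    protocols with their summary statistics; the paired-pulse-ratio
    (PPR) variance statistics used on paired-pulse electrophysiology
    recordings; and synthetic-data generators so that every analysis
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
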