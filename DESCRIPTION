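Package: lifnet
Title: Stationary Transfer Functions of Excitatory-Inhibitory Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing and classifying the stationary response of
    recurrent excitatory-inhibitory networks of leaky integrate-and-fire
    neurons at finite coupling. Provides the single-neuron diffusion
    approximation firing rate (Ricciardi transfer function) and inter-spike
    interval coefficient of variation with numerically stable scaled-erfc
    evaluation, self-consistent mean-field fixed points for one- and
    two-population network models with stability diagnostics and ablation of
    recurrent mean or noise, a perturbative expansion in the inverse coupling
    strength with classification of the admissible solution families
    (balanced, supersaturated, saturated and mixed branches), fixed-noise and
    power-law (supralinear stabilized network) rate-model counterparts, and a
    clock-driven spiking-network simulator with Poisson external drive for
    validating the theory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
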