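Package: cerac
Title: Spiking Cerebellar Actor-Critic Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates a cerebellar cortical microcircuit as a spiking
    actor-critic reinforcement learner in continuous time. Parallel fibers
    encode the task state on a tiled two-dimensional grid of Poisson
    generators, stellate cells read out the sign-inverted state value
    (the critic), Purkinje cell groups encode action avoidance (the actor),
    and a single climbing fiber delivers negative-reward spikes that gate
    eligibility-trace plasticity at parallel-fiber synapses without any
    explicit temporal-difference error computation. Includes leaky
    integrate-and-fire population dynamics, the full molecular-layer
    connectivity scheme, deep-nuclei action selection, the mountain car
    and delay eyeblink conditioning tasks, and a reproducible episode and
    training protocol with success-rate metrics and ablation switches.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
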