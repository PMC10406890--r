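Package: fepnet
Title: Reverse Engineering Generative Models from Neuronal Ensemble Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for validating the free-energy principle on trial-based
    neuronal recordings. Implements a discrete (POMDP-style) stimulus
    generating process for blind source separation experiments, an ideal
    variational Bayesian observer with categorical states and Dirichlet
    likelihood beliefs, a canonical rate-coding neural network whose
    activity and Hebbian/homeostatic plasticity descend a shared cost
    function equal to variational free energy, reverse engineering of the
    implicit generative model (state priors from firing-threshold factors,
    likelihood posteriors from effective synaptic connectivity), and
    prediction of future responses and plasticity from initial sessions
    only. A synthetic multielectrode-array recording generator emulates
    evoked spike-count data so the full analysis pipeline can be exercised
    and tested without external recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
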