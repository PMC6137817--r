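Package: corridortask
Title: Analysis of V1 Population Activity in a Virtual-Corridor Reward Task
Version: 0.1.0
Authors@R: person("Corridor", "Maintainer", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for analysing two-photon calcium-imaging recordings from
    head-fixed mice running a visually guided reward task in a virtual linear
    corridor. Provides a synthetic-session generator with planted neural
    tuning, behavioural metrics including a permutation-based spatial
    modulation index of licking, percentile-baseline dF/F0 extraction with
    zero-phase FIR smoothing, spatially binned response matrices, statistical
    classification of task-responsive, reward-location and gain-modulated
    neurons, and a template-matching population decoder with leave-one-out
    cross-validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
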