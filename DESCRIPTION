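Package: excitmargin
Title: Excitability-Margin Gating Scenarios for Ventral CA1 Pyramidal Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the neuronal excitability margin (spike threshold minus
    resting membrane potential) as a quantitative gating variable. Composes
    stress, inflammatory and reactivation-related pro-excitatory "hits" into
    named scenarios via a cumulative margin equation, runs one-at-a-time and
    combined-grid sensitivity sweeps, compares the residual effective margin
    against a catalog of physiologically reported transient depolarizing
    events (with analytic and Monte Carlo exceedance probabilities), and
    generates synthetic neuron populations for parameter-recovery testing.
    Includes report writers and a thin command-line entry point for
    reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
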