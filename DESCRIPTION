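Package: ntamp
Title: Nonlinear Transient Amplification in Recurrent E/I Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for nonlinear transient
    amplification (NTA) in recurrent excitatory-inhibitory rate networks
    with supralinear (rectified power-law) input-output functions.
    Implements fixed-step Euler simulation of single-ensemble dynamics with
    spike-frequency adaptation or Tsodyks-Markram-style short-term
    depression/facilitation, characteristic-function bifurcation analysis,
    Jacobian-based stability and inhibition-stabilized-network (ISN)
    diagnostics including the paradoxical effect, block-Jacobian
    eigenvalue theory for multi-ensemble networks with global or co-tuned
    inhibition, pattern-completion and pattern-separation metrics, and a
    conductance-based leaky integrate-and-fire spiking network with
    AMPA/NMDA/GABA synapses and short-term plasticity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
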