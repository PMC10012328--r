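Package: thetaSTDP
Title: Theta Phase-Gated Spike Timing-Dependent Plasticity in a Spiking
    Cortico-Hippocampal Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a small leaky integrate-and-fire network of neocortical
    and hippocampal neurons in which spike timing-dependent plasticity (STDP)
    is gated by opposing phases of an ongoing theta oscillation:
    potentiation traces are weighted toward the inhibitory theta phase and
    depression traces toward the excitatory phase, with burst thresholds that
    nullify singlet and doublet spike pairings.  Provides the two experimental
    protocols that constrain the model -- a theta-phase burst stimulation
    protocol in the style of hippocampal cell-culture experiments, and a
    multisensory theta-entrainment associative-memory paradigm with phase
    offset, modulation frequency, no-flicker and noise conditions -- plus
    lesioned model variants (theta-phase-only and STDP-only learning),
    windowed weight read-outs, a percentile-based memory decision index and
    least-squares model-comparison statistics against behavioural accuracy
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
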