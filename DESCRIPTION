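Package: drgtj
Title: Spike Propagation Through the Dorsal Root Ganglion T-Junction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biophysical multicompartment model of an unmyelinated (C-fiber)
    sensory neuron whose peripheral axon bifurcates at the dorsal root
    ganglion T-junction into a central axon and a stem axon leading to the
    soma. Implements the branched cable equation with Hodgkin-Huxley-style
    voltage-gated Na+ and delayed-rectifier K+ channels, slowly activating
    KCNQ (Kv7/M) channels, high-threshold Ca2+ channels, SK-type
    Ca2+-activated K+ channels, intracellular Ca2+ dynamics, Na+/K+
    concentration dynamics with an electrogenic pump, and a per-compartment
    leak reversal calibration. Provides frequency-domain input-impedance and
    voltage-transfer analysis of the passive tree, geometric-ratio
    calculations at the branch point, and an experiment layer measuring
    conduction velocity, spike-amplitude profiles, propagation reliability,
    following frequency, and ectopic (antidromic) spike generation under
    parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
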