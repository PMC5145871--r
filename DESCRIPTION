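Package: memvolt
Title: Transmembrane Voltage and Fusion-Pore Analysis for Closely Apposed
    Lipid Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Electrostatic analysis of two planar lipid bilayers brought into
    close contact, as occurs when a synaptic vesicle docks at the presynaptic
    membrane. Implements a closed-form five-layer slab model of the electric
    potential (charged membranes plus three neutralizing aqueous regions),
    the transmembrane voltage as a function of inter-membrane distance and
    lipid composition, and the critical distance at which the voltage reaches
    the electroporation threshold. A numerical route bins per-particle
    charges from coordinate files into one-dimensional density profiles and
    double-integrates the Poisson equation. A synthetic configuration
    generator emulates the layered simulation system, including plantable
    transmembrane pores whose radius follows reseal, stabilize or dilate
    schedules; grid-based detection measures pore sizes, formation times and
    fates, and lateral membrane tension is computed from box pressures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    minpack.lm,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
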