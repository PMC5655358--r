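Package: sdglu
Title: Spreading Depolarization with Glutamate Homeostasis in a Neuron-Glia-ECS Unit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biophysical single-unit model of spreading depolarization (SD)
    coupling Hodgkin-Huxley membrane dynamics, dynamic ion concentrations in
    neuron, glia and extracellular space, osmotic volume changes, and a
    glutamate release/diffusion/uptake subsystem with NMDA/AMPA receptor
    feedback. Includes experimental protocols (high-K+ perfusion,
    oxygen-glucose deprivation, impaired transporter uptake), stiff
    integration with SD event detection and uptake-rate scans, and a
    slow-fast bifurcation toolkit (fixed-point continuation in the slow
    potassium variable, Hopf/fold detection, critical cleft-glutamate
    levels, and the membrane-only subsystem).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: deSolve, stats, utils, grDevices, graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
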