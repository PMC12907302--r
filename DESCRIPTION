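Package: retinet
Title: Layered Network Simulation of the Retina and Early Visual System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable simulator for multi-layer networks of ODE-defined
    "Cells" (retinal neurons, cortical columns, prosthesis electrodes) coupled
    by typed synapses on generated lattice graphs. Grayscale movie stimuli are
    passed through a difference-of-Gaussians receptive-field front-end with
    fast recursive Gaussian filtering. Cell and synapse models are declarative:
    JSON definitions carrying vector-field equations in plain text are compiled
    at load time into evaluable R functions, so new models require no
    programming. Ships the standard retinal cell models (linear and
    gain-control bipolar/amacrine/ganglion cells, Morris-Lecar and
    Hodgkin-Huxley neurons, cortical mean-rate columns), typed synapse rules
    (cholinergic, rectified, linear, gap junction, ligand-gated,
    retino-cortical), six lattice connectivity generators with Gaussian weight
    profiles, axonal conduction delays, explicit fixed-step ODE solvers, and
    builders for retinal-wave, retino-cortical and Amari-Wilson-Cowan
    scenarios, plus a batch command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
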