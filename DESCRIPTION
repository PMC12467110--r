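Package: phonosim
Title: Desk-Scale Fluid-Structure-Acoustic Interaction Simulation of Phonation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced-order research simulator for voice production with
    subglottic stenosis. Couples an incompressible Navier-Stokes solver
    (Van Kan fractional step, collocated Cartesian grid, ghost-cell
    sharp-interface immersed boundaries) with the linearized perturbed
    compressible equations for acoustics (sixth-order compact differences,
    four-stage Runge-Kutta, anechoic buffers) and a plane-strain finite
    element model of the layered, transversely isotropic vocal folds,
    via explicit three-step coupling. Includes a parametric cosine
    stenosis deformation, idealized larynx fixtures, and a full phonatory
    analysis suite: phase averaging, glottal waveform quotients, sound
    pressure level and vocal efficiency, flow resistance, snapshot proper
    orthogonal decomposition of fold vibration, and source-filter formant
    extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tibble
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
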