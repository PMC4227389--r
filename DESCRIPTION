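Package: tdcsbidomain
Title: Multiscale Bidomain Simulation of Transcranial Direct Current
    Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Finite-element simulator coupling transcranial direct current
    stimulation (tDCS) volume conduction to neuronal membrane dynamics. The
    bidomain equations on the brain are coupled to a passive volume conductor
    in the extracerebral tissues and to FitzHugh-Nagumo membrane kinetics,
    and advanced in time with Godunov operator splitting: Heun's method for
    the reaction ordinary differential equations and an implicit-Euler P1
    finite-element solve of the coupled elliptic system, solved by conjugate
    gradients with a relaxed block-ILU(0) preconditioner. Includes a
    generator for a two-dimensional five-tissue concentric-annulus head
    phantom with a cerebrospinal-fluid channel, a Laplace volume-conductor
    reference solver with the same electrode boundary conditions, action
    potential conduction-velocity measurement, membrane depolarization
    ("AP sensitivity") maps, Gmsh mesh input/output, and legacy-VTK export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
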