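Package: gliomaIB
Title: Immersed-Boundary Simulation of Glioma Cell Infiltration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-dimensional multiscale simulator of glioma cell migration
    through a dense network of tethered normal glial cells. A glioma cell is
    represented as two elastic closed curves (membrane and nucleus) immersed
    in a viscous incompressible fluid and coupled to the flow by the immersed
    boundary method with an FFT-based spectral projection solver. Migration is
    driven by an elongation/retraction cycle with phase-dependent tethering
    and a chemotaxis-directed active force; confinement pressure sensed along
    the membrane feeds acto-myosin binding kinetics that soften the nucleus
    through a Hill-type stiffening rate, which is the mechanism that lets the
    cell squeeze its nucleus through intercellular gaps narrower than the
    nuclear diameter. Pulsed anti-invasion drug schedules (blebbistatin-like
    capping of bound myosin and inhibitors of actin-myosin association) are
    modeled as forced linear kinetics. Includes scenario builders for
    two-cell-gap, multilayer, zig-zag, turning-angle and astrocyte-pair
    geometries, published observables (cell-body and nucleus lengths, lateral
    nucleus deformation, speeds, pass/block classification), and parameter
    sweep drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), yaml, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
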