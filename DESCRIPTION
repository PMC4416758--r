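Package: mechanofate
Title: Mechano-Sensing Simulation of Stem Cell Fate on Elastic Substrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Agent-based simulator of a migrating spherical cell coupled to a
    three-dimensional linear-elastic finite element substrate. The cell probes
    substrate stiffness by exerting contractile sensing forces at its membrane
    nodes; the resulting internal deformation (mechanical signal) together with
    a maturation index drives mesenchymal stem cell differentiation into
    neuroblasts, chondrocytes or osteoblasts, as well as proliferation and
    apoptosis, as a function of the Young's modulus of the matrix. Includes a
    trilinear hexahedral elasticity solver, stochastic migration under a
    traction/protrusion/drag force balance, cell-cell contact rules, scenario
    presets for soft, intermediate and hard substrates, and CSV/VTK/JSON output.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
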