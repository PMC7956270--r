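Package: liqstruct
Title: Structural Analysis of Hydrogen-Bonded Liquid Mixtures Under Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing molecular configurations of water-methanol
    mixtures under periodic boundary conditions: partial radial distribution
    functions, Faber-Ziman partial structure factors and neutron-weighted total
    scattering structure factors, geometric hydrogen-bond detection, primitive
    (shortest-path) ring statistics, and modified Tait equation-of-state fits
    to pressure-density data. Includes seed-deterministic synthetic
    configuration generators (ideal gas, diamond hydrogen-bond networks,
    hard-core mixture packings, planted-ring graphs) with analytically known
    structure so every analysis stage can be validated without molecular
    dynamics output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
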