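Package: polimage
Title: Image-Charge Electrostatics and Like-Charge Attraction for Polarizable Spheres
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Electrostatics of one or two charged polarizable (dielectric)
    spheres by the image-charge method. Implements Neumann's image principle
    for a single sphere (Kelvin image plus line-image density), an exact
    three-point reformulation of the single-sphere polarization energy (two
    surface-point charges and a central image dipole, obtained through an
    incomplete beta function resummation), iterative image-reflection solvers
    for the two-sphere interaction energy and force, and closed-form
    first-level critical conditions that predict the onset of like-charge
    attraction, including the equal-size contact threshold 18/7 and phase
    diagrams in charge and size asymmetry. Ships a command-line interface for
    force curves, critical separations, phase diagrams and validation sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
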