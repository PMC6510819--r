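Package: kneefem
Title: Finite-Element Analysis of Intact and Torn Menisci Under Weight Bearing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained finite-element pipeline for tibiofemoral joint
    mechanics during the screw-home phase of knee flexion (0-30 degrees).
    Generates a parametric synthetic knee geometry (rigid bones, isotropic
    cartilage layers, transversely isotropic C-shaped menisci anchored by
    tension-only insertional-ligament springs), meshes it with linear
    tetrahedra, solves the static contact problem under axial compressive
    load with penalty Coulomb friction, inserts full-thickness longitudinal
    and radial meniscal tears by node duplication, and post-processes
    hoop-stress transects, tear-surface stress differences, tear-apex stress
    concentrations, compartmental contact metrics, and meniscal segment
    displacements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
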