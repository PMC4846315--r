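Package: furrow2d
Title: Differential-Tension Mechanics of the Early Drosophila Embryo
    Cross-Section
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-dimensional mechanical model of the early Drosophila
    embryo cross-section as a ring of quadrilateral cells with apical,
    basal and lateral surface tensions, incompressible cell and yolk
    areas, and confinement by a stiff vitelline membrane.  Minimum-energy
    shapes are found by augmented-Lagrangian constrained minimization;
    ventral furrow formation is driven by a quasi-static ramp of apical
    tension in the ventral cell population.  Includes phase-diagram
    sweeps over lateral and dorsal cortical tensions, in-silico
    cauterization (vertex-pinning) experiments, deformation observables
    (furrow depth, dorsal dilation, lateral displacement), simulated
    kymographs, tension inference from ablation-recoil speeds, and a
    seeded synthetic-data generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
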