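Package: ecogvolt
Title: Patient-Specific Volume-Conduction Modelling of Direct Electrocortical
    Stimulation on Synthetic Head Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model and validate the voltages generated on the cortical
    surface by direct electrocortical stimulation (DECS) through subdural
    electrocorticography (ECoG) grids. Generates synthetic head phantoms
    (nested tissue surfaces, gyral slabs, spherical heads), simulates
    post-implantation brain shift and CT-like electrode artifacts, implements
    three electrode projection methods (principal axis, Hermes, Dykstra
    energy minimisation) with configurable cerebrospinal-fluid depth, builds
    region-labelled tetrahedral meshes with an insulating silicone sheet and
    73-node electrode disks, solves the quasi-static Poisson volume-conduction
    problem with a Jacobi-preconditioned conjugate gradient solver, extracts
    quasi-static plateau voltages from biphasic stimulation pulse trains, and
    compares simulated against recorded voltages with regression, variance and
    paired nonparametric statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
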