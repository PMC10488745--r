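Package: mifqsar
Title: Structure-Based 3D-QSAR with Molecular Interaction Fields and PLS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A structure-based 3D-QSAR toolkit in the CoMFA tradition for
    congeneric small-molecule series such as synthetic cathinones acting at
    serotonin receptors. Provides docking-pose assessment (heavy-atom RMSD,
    pose classification, and the docking-accuracy statistic over
    re-docking and cross-docking stages), probe-based steric and electrostatic
    molecular interaction fields sampled on a common lattice, descriptor
    pretreatment (energy cutoff, zeroing, minimum-SD filtering) with grid-search
    optimization, NIPALS partial least squares with leave-one-out and
    leave-some-out cross-validation, Y-scrambling, fractional-factorial-design
    variable selection, external prediction metrics, and export of
    PLS-coefficient maps as Gaussian cube or OpenDX grids. A synthetic-data
    generator produces aligned series with planted field-activity relations
    and poses at controlled RMSD for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
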