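Package: sulcushape
Title: Surface-Based Morphometry of Cortical Sulci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Surface-based shape analysis of labeled cortical sulcus meshes,
    modelled on central-sulcus morphometry pipelines. Provides harmonic
    (steady-state heat equation) parameterization of sulcal ribbon meshes with
    ridge and endpoint boundary conditions, landmark-based piecewise-linear
    reparameterization and template correspondence, the inertial-plane signed
    distance sulcal profile, depth-position profiles, six global shape measures
    (length, average and maximum depth, span, surface area, cortical
    thickness), covariate-adjusted group statistics with Benjamini-Hochberg
    false discovery rate control, masked clinical-score correlations, and a
    synthetic sulcal-mesh cohort generator with analytic ground truth for
    validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0), methods
Imports: Matrix, stats, utils, jsonlite, xml2, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
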