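Package: asymvbm
Title: Voxel-Based Gray-Matter Asymmetry Analysis for Symptom-Defined Subgroups
Version: 0.1.0
Authors@R: person("VBM", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: End-to-end voxel-based morphometry of hemispheric gray-matter
    asymmetry in multi-site case-control cohorts. Provides symptom-scale
    normalization and dominance subgrouping (ADI-R or ADOS), matched-control
    selection, left-right flipping against a symmetric template, voxel-wise
    asymmetry-index maps with Gaussian smoothing, mass-univariate general
    linear models with age, gender and site covariates, Gaussian-random-field
    cluster-level inference, cluster-restricted brain-behavior and age
    regressions, and a synthetic multi-site cohort generator with known
    ground truth for calibration and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
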