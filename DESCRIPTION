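Package: voxbone
Title: Subject-Specific Bone Finite-Element Models from CT Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds subject-specific long-bone models from computed-tomography
    volumes: Hounsfield-unit to apparent-density calibration, density-driven
    material mapping under four constitutive representations (isotropic
    elastic, elastic-plastic, hyper-elastic Mooney-Rivlin, and transversely
    isotropic), a voxel hexahedral linear finite-element solver under gait
    loading, a binary damage (utilization) indicator, and cohort-level
    demographic statistics. Includes synthetic generators for femur-like CT
    phantoms, uniaxial test data, gait load curves, and demographic cohorts,
    so the whole pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
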