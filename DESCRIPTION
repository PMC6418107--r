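Package: hipFE
Title: Voxel Finite-Element Hip Load Capacity, QCT Calibration, and
    Overload Risk Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable pipeline for
    QCT-based assessment of proximal femur strength. Generates synthetic
    quantitative computed tomography (QCT) volumes of a parametric
    proximal femur with an in-field calibration phantom; calibrates
    Hounsfield units to equivalent mineral density and cross-calibrates
    between scanners; estimates hip load capacity by nonlinear voxel
    finite-element analysis in single-limb stance and posterolateral
    fall loading configurations with a density-dependent four-region
    stress-strain law and a von Mises effective-strain secant solver;
    derives percentile-based load-capacity cut-points and classifies
    subjects against combined DXA T-score / finite-element operating
    bands; and runs Monte-Carlo probabilistic risk assessment of the
    probability that mission- and activity-specific applied hip loads
    exceed an individual's load capacity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
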