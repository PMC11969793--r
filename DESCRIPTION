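Package: ttfplan
Title: Electrode-Position Optimization for Tumor-Treating-Fields Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-based treatment-planning toolkit for tumor-treating-fields
    (alternating electric field) therapy of abdominal tumors. Generates
    synthetic segmented abdominal phantoms, places paired transducer arrays
    on the body surface relative to the tumor centroid, solves the
    quasi-static conduction equation with inhomogeneous tissue conductivity
    by a conservative finite-volume discretization, and evaluates competing
    electrode montages through a rotation-scan protocol using mean/minimum
    tumor field, homogeneity index, coverage index and dose-volume
    histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
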