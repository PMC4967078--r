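Package: radstab
Title: Robustness of CT Density and Texture Features Across Dose and
    Reconstruction Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the eight-feature intensity-histogram battery and the
    eighteen-feature three-dimensional gray-level co-occurrence matrix (GLCM,
    Haralick) texture battery used in CT lung-nodule quantification, together
    with a reproducibility-to-repeatability ratio statistic (Q) that scores the
    stability of each feature under changes of dose level and reconstruction
    kernel. A synthetic CT generator emulates a uniform water phantom and
    heterogeneous lung nodules across a dose-by-kernel condition grid, with an
    image-domain dose-reduction surrogate, so the complete simulate, extract,
    analyze pipeline runs without patient data. Feature and condition rankings,
    nearest-condition matching, and per-condition summaries reproduce the
    structure of the robustness analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
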