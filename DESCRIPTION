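Package: kneelax
Title: Stress-MRI Quantification of Knee Joint Laxity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark- and segmentation-based quantification of knee joint
    laxity from stress MRI of the posterior drawer test. Computes 3D Euclidean
    vector measures between anatomic landmarks and between axis-surface
    intersection fixpoints on anisotropic sagittal-stack label volumes,
    automated analogues of the 2D manual reference measures (posterior tibial
    translation, meniscal displacement, anterior-posterior interval), delta
    tables against the unloaded intact baseline, repeated-measures ANOVA with
    Bonferroni post-hoc comparisons, paired-design power utilities, and the
    loading-device unit conversions. Includes a synthetic knee-phantom
    generator with ground-truth rigid kinematics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
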