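Package: femora
Title: Three-Dimensional Femoral Morphometry and Anteversion Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Measures the femoral anteversion angle, the femoral neck-shaft
    angle and the anterior-wall angle of the greater trochanter on
    triangulated proximal-femur surfaces: least-squares sphere fit of the
    head, narrowest-neck-section search, canal-centre shaft axis, a
    simulated trochanteric osteotomy cut with an anterior-wall tangent
    line, and signed projected angles in tabletop and ISB-style anatomical
    frames. Ships a parametric femur phantom generator with closed-form
    ground truth, a cohort simulator calibrated to published sex-specific
    marginals, and the statistical layer (intraclass correlation,
    correlation and group comparisons, Shapiro-Wilk gate, forced-entry
    multiple regression with Durbin-Watson and outlier diagnostics, and
    sex-specific anteversion prediction equations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    lmtest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
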