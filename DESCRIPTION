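Package: portalwss
Title: Reduced-Order Portal Venous Hemodynamics and Low Wall Shear Stress
    Scoring After Splenectomy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates post-splenectomy hemodynamics of the portal venous
    system on parametric vessel-network geometries and scores thrombosis
    risk by the area of low wall shear stress (ALWSS). Provides a
    reduced-order generalized-Newtonian tube-flow model (Carreau rheology
    with Weissenberg-Rabinowitsch-Mooney inversion), virtual splenectomy
    editing of the portal tree, area-weighted wall shear stress metrics,
    synthetic patient cohort generation with logistic thrombosis labels,
    and the evaluation statistics used to assess the score (empirical
    ROC/AUC, accuracy-optimal thresholding, Pearson correlation, Mood's
    median test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
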