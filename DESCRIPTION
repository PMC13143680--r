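Package: dkdflux
Title: Digital Urine Physicalomics and Serum-to-Urine Metabolic Flux
    Ratios for Early Diabetic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multi-modal early detection of diabetic
    kidney disease. Quantifies digital urine phenotypes from time-lapse
    cuvette images (CIELAB chromaticity with colour-card correction, foam
    half-life, micro-bubble index), computes double-creatinine-normalised
    serum-to-urine metabolite flux ratios with missingness filtering,
    KNN and LOD/2 imputation and dilution normalisation (PQN, TUS),
    fits OPLS-DA models with VIP scores and permutation validation, builds
    and evaluates tiered random-forest fusion classifiers (nested
    cross-validation, DeLong AUC comparison, calibration, NRI/IDI,
    decision-curve analysis, nomogram), and projects 3-year renal outcomes
    by Monte-Carlo simulation with Cox and Fine-Gray sensitivity analyses.
    A synthetic-data module generates cohorts, paired metabolite panels,
    outcome histories and rendered urine image phantoms with known ground
    truth so that every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    grDevices,
    utils,
    ranger,
    survival,
    cmprsk,
    pROC,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png,
    knitr,
    rmarkdown
Config/testthat/edition: 3
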