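Package: shuntpredict
Title: Predicting Ventriculoperitoneal Shunt Response in Idiopathic Normal
    Pressure Hydrocephalus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating preoperative predictors of ventriculoperitoneal
    shunt response in idiopathic normal pressure hydrocephalus (iNPH).
    Implements the CSF tap-test positivity criteria and the Krauss-index
    responder rule, scalar ventricular-geometry indices (Evans index, z-Evans
    index, brain-per-ventricle ratio, posterior horn ratio), rules for
    combining the tap test with imaging markers (DESH sign, callosal angle),
    diagnostic accuracy metrics with ROC curves and Youden-index cutoff
    selection, a univariate test cascade with a forward likelihood-ratio
    logistic regression, synthetic cohort simulation via a latent Gaussian
    copula, exact reconstruction of joint contingency structure from printed
    group-level counts, and an end-to-end multicenter analysis pipeline with
    leave-one-center-out sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
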