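Package: idvsim
Title: Monte Carlo Simulation-Convolution of Interfraction Dose Variations
    in HDR Brachytherapy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies the clinical effect of interfraction dose variations
    (IDVs) in high-dose-rate (HDR) brachytherapy for cervical cancer.
    Provides EQD2 dose arithmetic and reference logistic/probit tumour
    control (TCP) and normal-tissue complication (NTCP) dose-response
    curves; left-skewed Beta, generalized extreme value and normal IDV
    uncertainty distributions with residual-sum-of-squares ranking,
    Anderson-Darling testing and quantile-quantile export; a synthetic
    patient cohort generator with organ-at-risk IDV regressions; a Monte
    Carlo simulation-convolution engine that perturbs HDR prescriptions
    with sampled IDVs, simulates binary treatment outcomes and refits
    logistic dose-response curves by maximum likelihood; treatment failure
    rate statistics with replicate analysis; and a utility model
    U = TCP * (1 - NTCP) for optimal-dose and risk-free local control
    prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    nortest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
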