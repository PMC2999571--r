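Package: psavax
Title: Personalized Dynamical Models of Prostate Cancer Whole-Cell Vaccination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a seven-compartment ordinary-differential-equation model
    of allogeneic whole-cell vaccine immunotherapy in androgen-independent
    prostate cancer, with impulsive intradermal dosing. Calibrates the four
    patient-specific parameters (tumor growth rate, effector killing efficacy,
    and the PSA-tumor-burden scaling pair) to an individual's PSA time series
    by bounded multi-start least squares, validates predictions on held-out
    PSA measurements, grows the training set iteratively until predictions
    reach a target accuracy, and searches intensified vaccination regimens
    (graded dose increases, shortened dosing intervals) for the minimal change
    that stabilizes PSA. Includes a virtual-patient generator so the whole
    pipeline can be exercised and tested without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    withr
Config/testthat/edition: 3
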