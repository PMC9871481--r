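Package: coxdae
Title: Survival Prediction from Multimodal Brain MRI with a Cox Denoising Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prognostic modelling for glioblastoma from multimodal 3D MRI.
    Implements a convolutional denoising autoencoder whose hidden layer feeds a
    survival branch trained with the negative log partial likelihood of the Cox
    proportional-hazards model, yielding a per-patient prognostic index; plus
    volume-of-interest preprocessing from NIfTI input, an HDF5 cohort container,
    a synthetic tumour cohort generator with known hazard for validation, and a
    survival evaluation suite (Harrell concordance, risk-class accuracy,
    Kaplan-Meier and log-rank, Schoenfeld residual diagnostics, time-dependent
    ROC, and a Cox regression nomogram with calibration curves).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    survival,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: HDF5 (libhdf5)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
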