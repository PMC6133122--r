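Package: nephroNMR
Title: Urine NMR Metabolite Constellations for Kidney-Allograft Rejection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-phase modelling pipeline that derives and applies a urine
    1H-NMR metabolite rejection score for kidney-transplant monitoring.
    Phase one bins spectra into equal-width features (total-integral
    normalization, cubic-root transform, autoscaling) and ranks them by
    iterative random-forest feature selection.  Phase two quantifies a
    ten-metabolite candidate panel plus creatinine by pseudo-Voigt peak
    fitting with goodness-of-fit gating, enumerates all logistic models of
    up to five metabolites, filters them by cross-validated and test-set
    AUC plus a declarative rule cascade, and computes the final
    four-metabolite rejection score (alanine, citrate, lactate, urea,
    creatinine-normalized).  A synthetic-data module simulates urine
    spectra, transplant cohorts with BANFF-graded biopsies, and
    standardized feature tables so every stage is testable without
    clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    minpack.lm,
    ranger,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
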