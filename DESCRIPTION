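Package: mmbwqs
Title: Multi-Media Biomarker Weighted Quantile Sum Regression for Brain
    Network Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Links a four-metal (Mn, Pb, Cr, Cu) by four-medium (blood,
    urine, hair, saliva) exposure mixture to resting-state brain-network
    efficiency. Implements AR(1) pre-whitening and confound regression of
    ROI time series, weighted functional-connectome global and local
    efficiency, and a hierarchical two-level weighted quantile sum (WQS)
    "multi-media biomarker" regression with sign-constrained weights,
    bootstrap weight ensembles and repeated-holdout inference. Ships a
    fully synthetic cohort generator (log-normal censored biomarkers with
    cross-media correlation, modular AR(1) ROI time series) with known
    ground truth so every stage is testable without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
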