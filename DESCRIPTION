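Package: lspdetrend
Title: Seasonality Detection in Diagnosis-Code Incidence by Detrended
    Lomb-Scargle Periodograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects periodic (seasonal) patterns in monthly
    diagnosis-code incidence derived from electronic health record event
    tables. Monthly unique-patient counts per code are corrected for
    secular growth (de-trending by Gaussian kernel regression with
    automatic bandwidth) and for the shared seasonal oscillation in total
    hospital visits (de-totaling by subtracting a mean-scaled copy of the
    detrended total). Periodicity of the adjusted series is scored with
    Lomb-Scargle periodograms, false-alarm p-values from the exponential
    null, an 18-month period admissibility cutoff, and Benjamini-Hochberg
    control across codes. Includes hierarchical clustering of seasonal
    codes, a windowed case-control comorbidity screen with incidence
    ratios and Fisher exact tests, and a synthetic EHR event generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
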