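Package: coeliactriage
Title: Diagnostic Accuracy and Biopsy-Avoidance Economics for
    Point-of-Care Coeliac Screening in Iron Deficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating a point-of-care coeliac antibody test as
    a pre-endoscopy triage instrument in iron-deficient patients.
    Implements the coeliac case definition (Marsh 3a-3c villous atrophy
    with positive IgA-EMA or IgA-TTG serology, with HLA-DQ2/DQ8 used to
    resolve seronegative atrophy), exact diagnostic-accuracy panels with
    Clopper-Pearson intervals and likelihood ratios, prevalence-adjusted
    predictive values, a biopsy-avoidance cost model with per-100
    normalisation, prevalence sweeps and break-even analysis, a synthetic
    patient-cohort simulator with correlated test errors, and CSV/JSON
    input-output with an end-to-end report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
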