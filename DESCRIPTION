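Package: bfcat
Title: Bifactor Graded Response Model Calibration and Multidimensional
    Computerized Adaptive Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calibrates ordinal patient-reported outcome items under a
    bifactor graded response model by full-information maximum likelihood
    (Bock-Aitkin EM with bifactor dimension reduction), screens item pairs
    for local dependence with Yen's Q3 residual correlations, and simulates
    multidimensional computerized adaptive test (MCAT) administrations with
    determinant-rule (D-optimal) item selection, maximum a posteriori trait
    scoring, and factorial standard-error/theta-change stopping rules.
    Includes a synthetic-data generator emulating a 44-item
    health-related-quality-of-life bank with one general and ten group
    factors, and performance summaries (RMSD, correlation with true traits,
    item reduction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
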