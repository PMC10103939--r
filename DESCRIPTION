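Package: pepcsd
Title: Peptide Charge State Distributions from MS1 Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extraction and analysis of peptide charge state distributions
    (CSDs) from centroided MS1 spectra in electrospray-ionization LC-MS/MS
    experiments. Implements a stringent isotope-envelope extraction scheme
    with per-charge presence filters and intensity-weighted elution
    averaging, total-variation comparison of CSDs with one-parameter batch
    correction, monotone penalized-spline trends of mean charge versus mass
    stratified by basic-site count, and region-stratified intrinsic-basicity
    scores from fractional-response ridge logistic regression on amino-acid
    composition. Includes a synthetic LC-MS1 run simulator with ground-truth
    CSDs so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    mzR,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
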