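Package: ncaval
Title: Noncompartmental Pharmacokinetics and Bioanalytical Method Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Noncompartmental pharmacokinetic analysis of intravenous-bolus
    plasma concentration-time profiles (terminal-phase log-linear regression,
    trapezoidal AUC and AUMC with extrapolation to infinity, clearance, mean
    residence time and steady-state volume of distribution) together with the
    statistics of bioanalytical method validation for chromatographic assays:
    calibration-curve fitting and back-calculation, limits of detection and
    quantification, intra- and inter-day precision and accuracy, extraction
    recovery and stability, with the standard 15/20 percent acceptance rules.
    Includes a synthetic-data generator (sum-of-exponentials disposition,
    proportional plus additive assay noise, between-subject variability and
    quantification-limit censoring) so the whole pipeline is testable without
    animal data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pracma
Config/testthat/edition: 3
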