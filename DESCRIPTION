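Package: nirdecon
Title: Confounder-Aware Near-Infrared Calibration with PLS and sMC
    Variable Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Calibration of near-infrared (NIR) spectra measured on solid
    wood for a chemical trait (heartwood extractives content) in the
    presence of a physical confounder (grain angle of the scanned
    surface).  Provides spectral pre-treatments (standard normal variate,
    Savitzky-Golay derivatives), deterministic Kennard-Stone sample
    partitioning, PLS1 regression by NIPALS with leave-one-out
    cross-validation, per-wavenumber significance multivariate
    correlation (sMC) importance profiles, and a dual-response selection
    rule that keeps wavenumbers significant for the trait but not for
    the confounder.  Includes a synthetic NIR spectra generator with
    planted trait, confounder and shared absorption bands used as ground
    truth for validating the deconfounding workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
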