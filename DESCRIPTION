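Package: condwealth
Title: Conditional Wealth and Asset-Based Mobility for Longitudinal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construct temporally-harmonized household asset indices from ordinal
    asset, housing and utility items using polychoric principal components
    analysis, quantify changes in mean wealth, asset-based inequality and
    relative position across study waves of a closed cohort, decompose each
    wave's wealth into the component predicted by all prior waves and a
    conditional (unexplained-residual) component, and estimate associations of
    anchor wealth and wealth mobility with later-life outcomes under the
    adjustment rules appropriate for conditional measures. Includes a synthetic
    cohort generator with known latent wealth dynamics for parameter-recovery
    studies, and an end-to-end pipeline with CSV/JSON input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
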