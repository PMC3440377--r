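Package: cvreclass
Title: Population Impact of Replacing the Framingham Risk Score with the
    Reynolds Risk Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores primary-prevention cohorts with the Framingham hard
    coronary heart disease equation and the Reynolds Risk Score (both in
    ten-year Cox survival form), assigns ATP III risk categories and LDL-C
    treatment goals (Friedewald calculation with the non-HDL-C fallback),
    quantifies risk-category reclassification and its clinically significant
    subset (subjects whose LDL-C lies between the two scores' goals), and
    estimates population shares with design-based survey statistics
    (Taylor-linearized standard errors and Wald confidence intervals for
    stratified multistage samples). Includes a calibrated synthetic
    NHANES-like cohort generator with planted ground truth so the whole
    pipeline is testable without external downloads, plus readers for
    delimited and SAS transport inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    foreign,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
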