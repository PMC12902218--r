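Package: icmeval
Title: Evaluation of Insertable Cardiac Monitor Atrial Fibrillation Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation-based evaluation framework for atrial fibrillation (AF)
    detection by insertable cardiac monitors (ICMs) against gold-standard Holter
    annotations. Generates synthetic monitoring cohorts with controlled error
    modes (missed episodes, boundary jitter, cause-labelled false positives,
    uninterpretable segments, clock offset and drift), aligns the ICM and Holter
    clocks by interval-overlap maximization, and computes episode-, duration-
    and patient-based accuracy metrics under the standard exclusion rules, with
    gross, patient-average and cluster-adjusted (GEE) estimates and confidence
    intervals. Includes per-patient AF-burden agreement (Pearson correlation and
    Bland-Altman limits of agreement) and a 1-D convolutional neural network
    that classifies stored electrograms of device-detected episodes to reject
    false positives, with re-evaluation of every metric family after filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
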