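Package: uvsdt
Title: Unequal-Variance Signal Detection Profiling of Treatment Decisions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models binary treatment decisions as a criterion on a continuous
    decision driver under unequal-variance signal detection theory with
    logistic truth-state distributions. Fits the truth-state distributions by
    maximum likelihood (or a grid-posterior Bayesian variant), derives the
    double-logit ROC accuracy parameters (slope and intercept of the linear
    zROC), constructs likelihood-ratio utility curves with unbiased and
    expected-value-optimal decision criteria, and performs exhaustive
    leave-one-out and random-partition resampling inference with IQR-fence
    outlier screening, percentile intervals, and subgroup comparisons.
    Includes a synthetic cohort generator with known ground truth for
    validation, and reporting helpers that export the descriptive, parameter
    and criterion tables of a clinical decision-profiling analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), MASS, jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
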