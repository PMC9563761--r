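Package: walkbp
Title: Real-World Walking Activity Measures and Blood Pressure Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes minute-epoch step-count data from wearable activity
    monitors into wear/non-wear, active and sedentary time, extracts walking
    and sedentary bouts, and computes ten activity measures across four
    domains (activity volume, frequency, intensity, sedentary behavior).
    Provides a two-stage statistical procedure linking the activity measures
    to systolic blood pressure: variable selection by cross-validated lasso
    and exhaustive best-subset regression with intersection of the selected
    sets, followed by sequential (hierarchical) blockwise linear regression
    with change-in-R-squared F tests. Includes a synthetic-data generator
    that plants known ground truth (non-wear gaps, walking bouts, linear
    outcome models) so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, yaml, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), glmnet, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
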