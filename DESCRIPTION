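Package: hlinet
Title: Model-Assisted National Estimates of Home and Leisure Injuries
    from a Sentinel Emergency-Department Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extrapolates the national incidence of home and leisure
    injuries (HLIs) treated in emergency departments from a small sentinel
    hospital network, using nationwide hospital-discharge stay counts as
    auxiliary data.  Implements a separate ratio estimator driven by a
    two-level quasi-Poisson mixed model with a natural cubic spline age
    effect, a linear year trend and AR(1) within-unit correlation, fitted
    by penalized quasi-likelihood; marginal ratios with a lognormal
    random-effect correction; delta-method variances for national totals,
    crude rates and truncated age-standardized rates; ICD-10 based
    selection of injury-related hospital stays; generation of synthetic
    sentinel studies with known ground truth; and leave-one-hospital-out
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    nlme,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
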