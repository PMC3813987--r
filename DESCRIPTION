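Package: nttp
Title: Dose-Finding Designs for a Normalized Total Toxicity Profile Endpoint
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for phase I dose-finding trials that replace the binary
    dose-limiting toxicity endpoint with a quasi-continuous multiple-toxicity
    score, the normalized total toxicity profile (nTTP), computed as the
    Euclidean norm of clinician-elicited grade-by-type toxicity weights.
    Implements the quasi-likelihood continual reassessment method (QLCRM)
    with a one-parameter logistic model, the Bayesian quasi-CRM with an
    empiric model, the extended isotonic design, and the unified approach,
    all driven by the nTTP score, together with indifference-interval
    skeleton calibration, pooled-adjacent-violators isotonic regression,
    scenario construction from per-toxicity grade-probability matrices with
    exact moments by enumeration, and replicated-trial simulation of
    operating characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
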