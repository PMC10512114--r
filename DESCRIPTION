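Package: primo
Title: Prime Implicant Explanations for Random Forests via Ordered Decision Diagrams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles depth-limited random-forest classifiers into reduced
    ordered decision diagrams over the threshold-induced discretization of
    their continuous features, and computes shortest compatible
    prime-implicant (sufficient) explanations rendered as per-feature
    invariance ranges. Targets early prediction of clinically meaningful
    (>=7 percent) six-month weight loss from two weeks of self-monitoring
    data. Also provides two baseline explainability metrics (per-feature
    monotonicity percentages and best-worst case conditional proportions),
    a calibrated synthetic cohort generator with z-score to natural-unit
    feature mappings, and grouped-binomial / mixed-logit tooling for
    expert-agreement evaluation studies (odds ratios, likelihood-ratio
    tests, random-intercept models).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    utils,
    MASS,
    lme4
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
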