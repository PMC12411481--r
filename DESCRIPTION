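Package: tnbcCEA
Title: Cost-Effectiveness of First-Line Pembrolizumab Plus Chemotherapy in
    Advanced Triple-Negative Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-state (progression-free, progressed, dead) Markov cohort
    model of first-line pembrolizumab plus chemotherapy versus placebo plus
    chemotherapy for advanced triple-negative breast cancer, from the Chinese
    healthcare-system perspective. Provides parametric survival curve
    representation, right-censored maximum-likelihood fitting with AIC/BIC
    model selection, pseudo individual-patient-data reconstruction from
    digitized Kaplan-Meier coordinates, time-dependent transition-probability
    construction from fitted progression-free and overall survival curves,
    discounted cost and QALY accumulation, incremental cost-effectiveness
    ratios, one-way deterministic sensitivity analysis, probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves, and
    drug price-discount scenario analysis. A synthetic trial-data generator
    with known ground truth makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    survival,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
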