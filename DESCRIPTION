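Package: perfquant
Title: Quantitative First-Pass Myocardial Perfusion CMR, T1/ECV and Calcium Scoring
Version: 0.1.0
Authors@R: person("perfquant", "developers", role = c("aut", "cre"),
    email = "perfquant@example.org")
Description: End-to-end quantitative analysis of dual-sequence first-pass
    cardiovascular magnetic resonance (CMR) perfusion studies: a
    saturation-recovery spoiled-gradient-echo signal model converting
    proton-density-normalized intensities to gadolinium concentration,
    constrained Fermi-function deconvolution of tissue curves against an
    arterial input function to yield pixel-wise myocardial blood flow,
    global perfusion and myocardial perfusion reserve, MOLLI-based T1
    estimation with partition-coefficient and extracellular-volume
    computation, Agatston coronary calcium scoring of non-contrast CT,
    normality-gated two-group cohort statistics with covariate-adjusted
    group means, and seeded synthetic-data generators for every input so
    the whole pipeline can be exercised against known ground truth.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
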