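Package: qqum
Title: Measurement Uncertainty Budgets and Conformity Decisions for Quick
    Quantitative Immunoassays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: GUM-style measurement uncertainty evaluation for rapid
    quantitative ("QQ") immunochromatographic residue assays. Evaluates
    type A and type B standard uncertainties, combines them by the law of
    propagation of uncertainty (root sum of squares), expands with a
    coverage factor, and decomposes the budget into per-source percentage
    shares. Assesses conformity of a measurement interval against a
    maximum residue limit (compliant / non-compliant / inconclusive) and
    scores decision accuracy against reference truth. Includes the paired
    before-after statistical toolkit for operator-competency studies
    (Shapiro-Wilk gated paired t / Wilcoxon tests, Cohen's d_z, bootstrap
    confidence intervals for the inter-operator coefficient of variation,
    exact McNemar test) and seeded synthetic-data generators for pipetting
    replicates, paired operator cohorts, and near-MRL sample panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
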