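Package: pqtlmr
Title: Proteome-Wide Mendelian Randomization and Colocalization for
    Reproductive-Timing Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample Mendelian randomization and Bayesian colocalization
    toolkit for linking genetically predicted circulating protein levels to
    quantitative outcomes such as age at menarche and age at natural
    menopause. Provides cis-pQTL instrument selection with LD proxies and
    instrument-strength metrics (R-squared, F-statistic), Wald-ratio and
    multi-instrument MR estimators (IVW, MR-Egger, weighted median, weighted
    mode), Steiger directionality testing, Bayesian colocalization under the
    single-causal-variant assumption (H0-H4) with a sum-of-single-effects
    fine-mapper to relax it, a simplified multi-trait colocalization,
    two-step mediation with Sobel inference, multivariable MR, analytic
    power calculations, and a synthetic GWAS summary-statistics generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
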