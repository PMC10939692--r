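Package: tidymr
Title: Tidy Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample Mendelian randomization built from first principles on
    GWAS summary statistics: per-SNP Wald ratios, fixed- and multiplicative
    random-effects inverse-variance-weighted (IVW) meta-analysis, the weighted
    median estimator with parametric-bootstrap standard errors, MR-Egger
    regression with its directional-pleiotropy intercept test, Cochran's Q and
    I-squared heterogeneity statistics, and per-instrument strength diagnostics
    (variance explained and F-statistics). Includes allele harmonization with
    palindromic-SNP handling, a pipeline over one exposure and many outcomes
    that emits machine-readable results and forest-plot tables, a synthetic
    summary-statistics generator for parameter-recovery testing, and bundled
    instruments for the causal effect of educational attainment on bone
    mineral density at four skeletal sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
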