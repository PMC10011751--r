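Package: meffpower
Title: Effective Number of Tests Correction and Power Analysis for
    Correlated Trial Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intervention studies that record a suite of
    correlated outcome measures. Computes the effective number of
    independent tests (MEff) from the eigenvalues of the outcome
    correlation matrix and the corresponding adjusted per-outcome alpha,
    alongside Bonferroni and Sidak thresholds; generates lookup tables of
    adjusted alphas over grids of outcome counts and mean
    intercorrelations; simulates two-group multivariate outcomes from
    one- or two-factor latent variable models with controlled mean
    intercorrelation and standardized effect size; estimates familywise
    error and power by Monte Carlo for Bonferroni, MEff and
    first-principal-component decision rules; and re-evaluates published
    studies' per-outcome p-values under each correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
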