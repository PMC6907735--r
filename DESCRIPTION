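Package: sumpca
Title: Covariate-Adjusted Regression and Phenotype PCA from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs covariate-adjusted multiple-regression results
    (coefficients, standard errors, p-values) for single genetic markers from
    per-marker simple-regression summary statistics, without access to
    subject-level data. Supports arbitrary linear combinations of phenotypes
    and regressions of phenotype principal-component scores, recovering
    raw-data ordinary least squares to machine precision when sample genotype
    moments and the phenotype covariance matrix are available, and providing
    a slope-correlation approximation of the phenotype covariance when it is
    not. Includes a synthetic biobank simulator, a subject-level OLS oracle,
    and an error-report framework for validating the reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
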