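Package: kinlmm
Title: Linear Mixed Models with Custom Relationship Covariance for Family Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits Gaussian linear mixed models in which random effects carry
    user-supplied (possibly positive semi-definite and sparse) covariance
    matrices, such as the additive genetic relationship matrix derived from a
    pedigree. Supports restricted and ordinary maximum likelihood with box and
    equality constraints on variance parameters, heritability estimation with
    profile-deviance confidence intervals, simulation-based restricted
    likelihood ratio tests, sex-specific (gene-environment interaction)
    variance models with heteroscedastic residuals, and per-SNP association
    scans against a structured null model, including a fast two-step mode with
    frozen variance components. A simulator generates pedigrees, gene-dropped
    genotypes, and phenotypes under every supported variance architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minqa,
    jsonlite,
    stats,
    utils,
    methods,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4
Config/testthat/edition: 3
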