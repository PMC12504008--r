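Package: cotwin
Title: Co-Twin Control Analysis of Education and Dementia Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for co-twin control analyses of educational attainment and
    dementia. Simulates twin cohorts under a bivariate ACE liability model
    with known ground truth; harmonizes ISCED education codes, registry
    onset ages, and latent-dementia-index (LDI) dementia calls; analyses
    education-discrepant twin and matched unrelated pairs; fits
    between-within generalized linear mixed models with zygosity-specific
    random-intercept variances by adaptive Gauss-Hermite quadrature; and
    encodes the decision rules separating quasi-causal effects from genetic
    and shared-environmental familial confounding, including discordant-pair
    sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    lme4,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
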