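Package: giniCCA
Title: Canonical Correlation Analysis for Binary Clinical Data with
    Gini Association Matrices
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate association analysis between two sets of binary
    clinical indicators (e.g. exposure/demographic variables versus
    symptom/diagnostic variables in an epidemiological cohort).
    Variance-covariance and correlation matrices for categorical data are
    built from a generalization of Gini's definition of variance
    (likeability), with pairwise-available-case handling of missing
    values.  Canonical correlation analysis on these matrices yields
    canonical variates, loadings, cross-loadings and redundancy
    coefficients; significance of the variates is assessed by row
    permutation with a sequential Wilks-type statistic, and uncertainty
    by subject-level bootstrap.  A latent-threshold (Gaussian copula)
    generator simulates binary cohorts with prescribed prevalences,
    missingness and a controllable between-set canonical correlation,
    including a preset emulating a 208-patient encephalitis cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), methods, SummarizedExperiment
Imports: stats, utils, MASS, S4Vectors, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
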