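# giniCCA

Canonical correlation analysis (CCA) for **binary clinical data**, built for
epidemiological risk-factor studies where two blocks of 0/1 indicators are
measured on the same subjects — e.g. exposure/demographic variables
(X block) versus symptom, clinical and diagnostic variables (Y block) in an
encephalitis cohort — and where individually weak pairwise correlations can
hide a strong multivariate association between the blocks.

## The method

Standard covariance assumes interval-scale data, so association between
binary variables is measured with the Gini-index (likeability)
generalization of variance: over the `m` subjects complete for a pair of
variables,

    V_ij = (1 / 2m²) Σ_a Σ_b (x_ia − x_ib)(x_ja − x_jb),
    R_ij = V_ij / √(V_ii V_jj),

computed entrywise on pairwise-available cases when values are missing
(per-pair complete-case counts are retained).  For 0/1 indicators `V_ii`
equals `p(1 − p)`.  CCA on the resulting blocks `S_xx`, `S_yy`, `S_xy`
solves

    (S_xx⁻¹ S_xy S_yy⁻¹ S_yx − λI) a = 0,
    (S_yy⁻¹ S_yx S_xx⁻¹ S_xy − λI) b = 0,

yielding `K = min(p, q)` canonical variate pairs with correlations
`ρ_k = √λ_k`, canonical loadings (a variable's correlation with its own
variate; its square × 100 is the percent of variation contributed),
cross-loadings (`ρ_k ×` loading) and redundancy coefficients (mean squared
Y-loading × `λ_k`).  Significance of each variate is tested by permuting
Y-block rows against X-block rows and comparing the sequential Wilks-type
statistic `Λ_k = Π_{j≥k}(1 − λ_j)` over (by default) 10,000 permutations;
standard errors of `ρ_k` come from a subject-level bootstrap.  A
latent-threshold (Gaussian copula) generator simulates binary cohorts with
prescribed prevalences, missingness and a controllable between-set
canonical correlation, including a preset emulating a 208-patient
encephalitis reference cohort (15 X and 24 Y variables).

## Worked example

```r
library(giniCCA)

ct <- generateCohort(encephalitisPreset(seed = 1))
ct
#> CohortTable: 208 subjects, 15 exposure (X) and 24 outcome (Y) variables
#>   missing cells: 5.6%

res <- runPipeline(ct, outDir = NULL, nPerm = 10000, nBoot = 1000, seed = 1)
res$inference
#> InferenceResult: 15 canonical variate(s), 10000 permutations (seed 1)
#>     rho    se      p
#> 1 0.666 0.049 0.0438
#> 2 0.589 0.034 0.0927
#> 3 0.511 0.031 0.1390
#> 4 0.494 0.033 0.1120
#> 5 0.468 0.032 0.1460
#>   ...
```

The 15 X / 24 Y structure gives 15 canonical variates; only the first is
significant at the 5% level here (`ρ̂₁ = 0.67`, bootstrap se 0.05,
permutation p = 0.044): the exposure and symptom blocks are strongly
associated through their first canonical pair, even though the largest
single between-set correlation in this cohort is far smaller.  The loadings
show which variables carry the pair:

```r
df <- structuralCoefficients(res$solution, variates = 1)
head(df[order(-abs(df$loading)), c("variable", "set", "loading", "percentContribution")], 5)
#>                 variable set loading percentContribution
#> 2             Age (<=10)   X   0.600                35.9
#> 38 Hospital Stay (<=50d)   Y   0.525                27.6
#> 18          Abnormal EEG   Y   0.436                19.0
#> 8       Recent Infection   X  -0.353                12.5
#> 4              Tick Bite   X   0.335                11.2
```

Age dominates the exposure side (36% of its variate's variation), and the
redundancy coefficients (here 1.7%, 2.0%, 1.1% for the first three
variates) show that the exposure variates explain only a small share of the
total symptom-block variance — a strong canonical pair does not imply bulk
predictability of symptoms from exposures.  With `outDir` set,
`runPipeline()` additionally writes descriptive statistics, the labeled
covariance/correlation/pairwise-n matrices, a per-variate loadings table, a
ranked text report for the first variate, and a `manifest.yaml` recording
the seed and any positive-semidefinite repairs; reruns with the same seed
are byte-identical.

Real data enter through `readCohort()` (subjects × variables CSV of 0/1
values plus a YAML set-assignment config, with optional threshold rules for
dichotomizing numeric columns such as age ≤ 10 years or hospital stay ≤ 50
days) or `runPipelineFromConfig()`.

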