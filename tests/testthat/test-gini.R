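test_that("pairwise Gini covariance matches the brute-force double sum", {
  # frozen worked examples (brute-force double sum computed in helper)
  expect_equal(giniPairCovariance(c(0, 1), c(0, 1)), 0.25)
  expect_equal(giniPairCovariance(c(1, 1, 1), c(0, 1, 0)), 0)       # constant x
  expect_equal(giniPairCovariance(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_equal(giniPairCovariance(c(1, 1, 0, 0), c(1, 1, 0, NA)), 2 / 9)
  expect_equal(giniPairCovariance(c(1, 1, 0, 0), c(1, 0, 0, 0)), 0.125)

  set.seed(41)
  for (rep in 1:20) {
    x <- rbinom(12, 1, 0.5); y <- rbinom(12, 1, 0.4)
    if (rep > 10) y[sample(12, 3)] <- NA   # exercise pairwise deletion
    if (var(x) == 0 || all(is.na(y))) next
    expect_equal(giniPairCovariance(x, y), bruteGini(x, y), tolerance = 1e-12)
  }
  expect_error(giniPairCovariance(c(1, NA, 0), c(NA, 1, NA)),
               "fewer than 2 complete cases")
})

test_that("Gini covariance equals product-moment covariance with divisor m on complete data", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(10:40, 1)
    ct <- randomBinaryTable(n, p = 2, q = 3)
    m <- cohortMatrix(ct)
    if (any(apply(m, 2, var) == 0)) next
    am <- giniCovariance(ct)
    mc <- cov(m) * (n - 1) / n        # centered cross-product, divisor m
    expect_equal(unname(giniV(am)), unname(mc), tolerance = 1e-12)
    # diagonal law V_ii = p_i (1 - p_i)
    prev <- colMeans(m)
    expect_equal(unname(diag(giniV(am))), unname(prev * (1 - prev)),
                 tolerance = 1e-12)
    expect_true(all(pairwiseN(am) == n))
  }
})

test_that("Gini matrix agrees with the brute-force double sum under missingness", {
  set.seed(7)
  m <- matrix(rbinom(80, 1, 0.5), 20, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  m[sample(80, 12)] <- NA
  ct <- CohortTable(m, sets = c("X", "X", "Y", "Y"))
  am <- giniCovariance(ct)
  expect_equal(giniV(am), bruteGiniMatrix(m), tolerance = 1e-12)
  expect_true(all(pairwiseN(am) == crossprod(!is.na(m))))
  expect_true(all(pairwiseN(am) <= 20))
})

test_that("correlation matrix has unit diagonal and the R_ij formula", {
  m <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 0, 0),
             c = c(0, 0, 1, 1), d = c(1, 1, 0, 0))
  ct <- CohortTable(m, sets = c("X", "X", "Y", "Y"))
  R <- giniR(giniCorrelation(giniCovariance(ct)))
  expect_equal(unname(diag(R)), rep(1, 4))
  expect_equal(R["a", "b"], 0.125 / sqrt(0.25 * 0.1875))  # 0.5774
  expect_equal(R["a", "d"], 1)    # identical columns
  expect_equal(R["a", "c"], -1)   # perfectly anti-aligned
  expect_true(all(abs(R) <= 1 + 1e-12))
})

test_that("zero-variance variables are flagged and their correlations zeroed", {
  m <- cbind(a = c(1, 0, 1, 0), z = c(1, 1, 1, 1), b = c(1, 1, 0, 0))
  ct <- CohortTable(m, sets = c("X", "X", "Y"))
  expect_warning(am <- giniCovariance(ct), "zero-variance")
  expect_identical(am@zeroVariance, c(FALSE, TRUE, FALSE))
  R <- giniR(suppressWarnings(giniCorrelation(giniCovariance(ct))))
  expect_equal(unname(R["z", c("a", "b")]), c(0, 0))
  expect_equal(R["z", "z"], 1)
})

test_that("a pair with < 2 complete cases names the offending pair", {
  m <- cbind(a = c(1L, 0L, NA, NA), b = c(NA, NA, 1L, 0L),
             c = c(1L, 0L, 1L, 0L))
  ct <- CohortTable(m, sets = c("X", "X", "Y"))
  expect_error(giniCovariance(ct),
               "pair \\('[ab]', '[ab]'\\) has fewer than 2 complete cases")
})

test_that("pairwise MCAR estimates converge to complete-data values", {
  set.seed(11)
  n <- 4000
  ct <- randomBinaryTable(n, p = 2, q = 2, prevRange = c(0.3, 0.7))
  m <- cohortMatrix(ct)
  Vfull <- giniV(giniCovariance(ct))
  mMiss <- m
  mMiss[matrix(runif(length(m)) < 0.2, n)] <- NA
  Vmiss <- giniV(giniCovariance(CohortTable(mMiss, sets = variableSets(ct))))
  # Monte-Carlo bound: covariance entries have SE ~ 1/sqrt(0.64 n) < 0.02
  expect_lt(max(abs(Vmiss - Vfull)), 3 * 0.02)
})

test_that("independent columns give near-zero Gini covariance at scale", {
  set.seed(5)
  n <- 10000
  m <- cbind(x = rbinom(n, 1, 0.5), y = rbinom(n, 1, 0.5))
  ct <- CohortTable(m, sets = c("X", "Y"))
  # binomial sampling bound: SE of the cross-covariance is 0.25/sqrt(n)
  expect_lt(abs(giniV(giniCovariance(ct))["x", "y"]), 3 * 0.25 / sqrt(n))
})

test_that("non-identity transformations are rejected in this release", {
  ct <- randomBinaryTable(10, 1, 1)
  expect_error(giniCovariance(cohortMatrix(ct), sets = c("X", "Y"), L = "fancy"),
               "identity")
})
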