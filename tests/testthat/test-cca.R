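test_that("univariate CCA is the absolute correlation; independence gives zero", {
  # p = q = 1: rho equals |r|
  V <- matrix(c(0.25, -0.1, -0.1, 0.21), 2, 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  sol <- solveCCA(AssociationMatrices(V, sets = c("X", "Y")))
  expect_equal(canonicalCorrelations(sol), 0.1 / sqrt(0.25 * 0.21),
               tolerance = 1e-10)

  # S_xy = 0: all canonical correlations vanish
  cfg <- local({set.seed(1); randomCovConfig(3, 4)})
  V0 <- cfg$V
  V0[cfg$sets == "X", cfg$sets == "Y"] <- 0
  V0[cfg$sets == "Y", cfg$sets == "X"] <- 0
  sol0 <- solveCCA(AssociationMatrices(V0, sets = cfg$sets))
  expect_equal(canonicalCorrelations(sol0), rep(0, 3), tolerance = 1e-8)
})

test_that("canonical correlations match the whitened-SVD oracle", {
  set.seed(99)
  for (rep in 1:50) {
    p <- sample(1:6, 1); q <- sample(1:6, 1)
    cfg <- randomCovConfig(p, q)
    am <- AssociationMatrices(cfg$V, sets = cfg$sets)
    sol <- solveCCA(am)
    expect_equal(canonicalCorrelations(sol),
                 svdCCA(Sxx(am), Syy(am), Sxy(am)), tolerance = 1e-10)
    # weights normalized to unit variate variance
    A <- canonicalWeights(sol, "X"); B <- canonicalWeights(sol, "Y")
    expect_equal(unname(diag(t(A) %*% Sxx(am) %*% A)), rep(1, sol@K),
                 tolerance = 1e-8)
    expect_equal(unname(diag(t(B) %*% Syy(am) %*% B)), rep(1, sol@K),
                 tolerance = 1e-8)
  }
})

test_that("both eigenvalue problems yield identical nonzero eigenvalues", {
  set.seed(3)
  for (rep in 1:20) {
    p <- sample(2:6, 1); q <- sample(2:6, 1)
    cfg <- randomCovConfig(p, q)
    ix <- cfg$sets == "X"
    Sxx <- cfg$V[ix, ix]; Syy <- cfg$V[!ix, !ix]; Sxy <- cfg$V[ix, !ix]
    lamX <- eigen(solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy),
                  only.values = TRUE)$values
    lamY <- eigen(solve(Syy) %*% t(Sxy) %*% solve(Sxx) %*% Sxy,
                  only.values = TRUE)$values
    K <- min(p, q)
    expect_equal(sort(Re(lamX), decreasing = TRUE)[1:K],
                 sort(Re(lamY), decreasing = TRUE)[1:K], tolerance = 1e-10)
  }
})

test_that("canonical correlations are invariant to within-set recoding", {
  set.seed(21)
  ct <- randomBinaryTable(300, p = 3, q = 4)
  am <- giniCovariance(ct)
  rho0 <- canonicalCorrelations(solveCCA(am))
  # apply random invertible transforms to each block of the covariance
  for (rep in 1:5) {
    Tx <- matrix(rnorm(9), 3) + diag(3)
    Ty <- matrix(rnorm(16), 4) + diag(4)
    V <- giniV(am)
    ix <- variableSets(am) == "X"
    V2 <- V
    V2[ix, ix] <- Tx %*% V[ix, ix] %*% t(Tx)
    V2[!ix, !ix] <- Ty %*% V[!ix, !ix] %*% t(Ty)
    V2[ix, !ix] <- Tx %*% V[ix, !ix] %*% t(Ty)
    V2[!ix, ix] <- t(V2[ix, !ix])
    rho2 <- canonicalCorrelations(solveCCA(
      AssociationMatrices(V2, sets = unname(variableSets(am)))))
    expect_equal(rho2, rho0, tolerance = 1e-8)
  }
})

test_that("the leading canonical correlation dominates every between-set pairwise correlation", {
  set.seed(13)
  for (rep in 1:10) {
    ct <- randomBinaryTable(150, p = 4, q = 5)
    am <- giniCorrelation(giniCovariance(ct))
    rho1 <- canonicalCorrelations(solveCCA(am))[1]
    R <- giniR(am)
    ix <- variableSets(am) == "X"
    expect_gte(rho1 + 1e-10, max(abs(R[ix, !ix])))
  }
})

test_that("scores reproduce the canonical correlations and propagate missingness", {
  set.seed(8)
  ct <- randomBinaryTable(200, p = 3, q = 3)
  sol <- solveCCA(ct)
  sc <- canonicalScores(ct, sol)
  for (k in seq_len(sol@K))
    expect_equal(abs(cor(sc$U[, k], sc$V[, k])), sol@rho[k], tolerance = 1e-8)

  # a missing X cell blanks that subject's U score, not V
  m <- cohortMatrix(ct)
  m[5, which(unname(variableSets(ct)) == "X")[1]] <- NA
  ct2 <- CohortTable(m, sets = variableSets(ct))
  sol2 <- solveCCA(ct2)
  sc2 <- canonicalScores(ct2, sol2)
  expect_true(all(is.na(sc2$U[5, ])))
  expect_false(anyNA(sc2$V[5, ]))

  # permuting rows permutes scores identically
  perm <- sample(nSubjects(ct))
  ct3 <- CohortTable(cohortMatrix(ct)[perm, ], sets = variableSets(ct))
  sc3 <- canonicalScores(ct3, sol)
  expect_equal(unname(sc3$U), unname(sc$U[perm, ]), tolerance = 1e-12)
})

test_that("cross-loadings obey cross = rho * loading and redundancy its formula", {
  set.seed(17)
  ct <- randomBinaryTable(250, p = 4, q = 6)
  sol <- solveCCA(ct)
  for (set in c("X", "Y")) {
    L <- canonicalLoadings(sol, set)
    Cx <- crossLoadings(sol, set)
    expect_equal(Cx, sweep(L, 2, sol@rho, `*`), tolerance = 1e-8)
    expect_true(all(abs(L) <= 1 + 1e-8))
  }
  redY <- redundancyCoefficients(sol, "Y")
  expect_equal(redY, colMeans(canonicalLoadings(sol, "Y")^2) * sol@lambda,
               tolerance = 1e-12)
  expect_true(all(redY >= 0 & redY <= sol@lambda + 1e-12))

  # single-variable Y attains the upper bound: redundancy = lambda
  ct1 <- randomBinaryTable(300, p = 3, q = 1)
  sol1 <- solveCCA(ct1)
  expect_equal(unname(redundancyCoefficients(sol1, "Y")), sol1@lambda,
               tolerance = 1e-10)
})

test_that("redundancy arithmetic on hand-set loadings", {
  # mean squared loading times lambda: ((0.36 + 0.64 + 0) / 3) * 0.25
  expect_equal(mean(c(0.6, 0.8, 0)^2) * 0.25, 0.0833333, tolerance = 1e-6)
})

test_that("loading contribution arithmetic follows the squared-loading rule", {
  lc <- loadingContributions(c(age = 0.94, wcc = -0.52), rho = 0.71)
  expect_equal(round(lc["age", "percentContribution"]), 88)
  expect_equal(round(lc["wcc", "percentContribution"]), 27)
  expect_equal(round(lc["age", "percentCross"]), 45)
  df <- structuralCoefficients(solveCCA(randomBinaryTable(100, 2, 2)))
  expect_equal(df$percentContribution, 100 * df$loading^2)
})

test_that("sign convention makes the dominant X loading positive", {
  set.seed(30)
  for (rep in 1:5) {
    sol <- solveCCA(randomBinaryTable(120, p = 3, q = 4))
    L <- canonicalLoadings(sol, "X")
    for (k in seq_len(sol@K))
      expect_gte(L[which.max(abs(L[, k])), k], 0)
  }
})

test_that("indefinite pairwise-deleted matrices are repaired and logged", {
  # force indefiniteness: an inconsistent correlation-like matrix
  V <- diag(3) * 0.25
  V[1, 2] <- V[2, 1] <- 0.24
  V[1, 3] <- V[3, 1] <- 0.24
  V[2, 3] <- V[3, 2] <- -0.24
  dimnames(V) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_lt(min(eigen(V, symmetric = TRUE)$values), 0)
  sol <- solveCCA(AssociationMatrices(V, sets = c("X", "X", "Y")))
  expect_true(any(grepl("PSD repair", sol@repairLog)))
  expect_true(all(sol@rho >= 0 & sol@rho <= 1))
})
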