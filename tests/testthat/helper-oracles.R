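## Independent oracles used across the suite.  These deliberately avoid the
## package's computational paths: the Gini covariance oracle is the literal
## pairwise-difference double sum, and the CCA oracle is the whitened SVD of
## the cross-covariance.

## 1/(2m^2) * sum_a sum_b (x_a - x_b)(y_a - y_b) over complete pairs.
bruteGini <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  m <- length(x)
  s <- 0
  for (a in seq_len(m))
    for (b in seq_len(m))
      s <- s + (x[a] - x[b]) * (y[a] - y[b])
  s / (2 * m^2)
}

bruteGiniMatrix <- function(m) {
  d <- ncol(m)
  V <- matrix(0, d, d, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(d))
    for (j in seq_len(d))
      V[i, j] <- bruteGini(m[, i], m[, j])
  V
}

## Canonical correlations as singular values of Sxx^{-1/2} Sxy Syy^{-1/2}.
symInvSqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (1 / sqrt(pmax(e$values, .Machine$double.eps)) * t(e$vectors))
}

svdCCA <- function(Sxx, Syy, Sxy) {
  d <- svd(symInvSqrt(Sxx) %*% Sxy %*% symInvSqrt(Syy), nu = 0, nv = 0)$d
  pmin(sort(d, decreasing = TRUE)[seq_len(min(nrow(Sxx), nrow(Syy)))], 1)
}

## Random joint PSD covariance configuration with p X- and q Y-variables.
randomCovConfig <- function(p, q) {
  d <- p + q
  A <- matrix(rnorm((d + 5) * d), d + 5, d)
  V <- crossprod(A) / (d + 5)
  dimnames(V) <- list(paste0("v", 1:d), paste0("v", 1:d))
  list(V = V, sets = rep(c("X", "Y"), c(p, q)))
}

## Random complete binary cohort with moderate prevalences.
randomBinaryTable <- function(n, p, q, prevRange = c(0.2, 0.8)) {
  d <- p + q
  prev <- runif(d, prevRange[1], prevRange[2])
  m <- sapply(prev, function(pr) rbinom(n, 1L, pr))
  colnames(m) <- paste0("v", seq_len(d))
  CohortTable(m, sets = rep(c("X", "Y"), c(p, q)))
}
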