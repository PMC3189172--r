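## Run fn with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  fn()
}

## Squared canonical correlations of a 0/1/NA matrix split into X/Y blocks:
## pairwise-complete Gini covariance, block PSD clipping, eigen solve.
.fitLambdas <- function(m, sets) {
  pc <- .giniCovPairwise(m)
  if (min(pc$N) < 2) stop("a pair has fewer than 2 complete cases")
  ix <- sets == "X"; iy <- sets == "Y"
  Sxx <- .psdClip(pc$V[ix, ix, drop = FALSE], "S_xx")$S
  Syy <- .psdClip(pc$V[iy, iy, drop = FALSE], "S_yy")$S
  .ccaLambdas(Sxx, Syy, pc$V[ix, iy, drop = FALSE])
}

## Precomputed machinery for permuting Y-block rows against X-block rows.
## S_xx and S_yy are invariant under a whole-row permutation of Y (the
## within-set missingness patterns travel with the rows), so only the
## between-set block is recomputed per permutation.
.permMachine <- function(X, Y) {
  n <- nrow(X)
  complete <- !anyNA(X) && !anyNA(Y)
  SxxInv <- NULL; SyyInv <- NULL
  pcX <- .giniCovPairwise(X); pcY <- .giniCovPairwise(Y)
  if (min(pcX$N) < 2 || min(pcY$N) < 2)
    stop("a within-set pair has fewer than 2 complete cases")
  Sxx <- .psdClip(pcX$V, "S_xx")$S
  Syy <- .psdClip(pcY$V, "S_yy")$S
  SxxInv <- solve(Sxx); SyyInv <- solve(Syy)
  if (complete) {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    Yc <- scale(Y, center = TRUE, scale = FALSE)
    crossCov <- function(idx) crossprod(Xc, Yc[idx, , drop = FALSE]) / n
  } else {
    Mx <- !is.na(X); X0 <- X; X0[!Mx] <- 0
    My <- !is.na(Y); Y0 <- Y; Y0[!My] <- 0
    storage.mode(Mx) <- "double"; storage.mode(X0) <- "double"
    storage.mode(My) <- "double"; storage.mode(Y0) <- "double"
    crossCov <- function(idx) {
      Myp <- My[idx, , drop = FALSE]; Y0p <- Y0[idx, , drop = FALSE]
      N <- crossprod(Mx, Myp)
      if (min(N) < 2) stop("a between-set pair has fewer than 2 complete cases")
      crossprod(X0, Y0p) / N -
        (crossprod(X0, Myp) / N) * (crossprod(Mx, Y0p) / N)
    }
  }
  lambdas <- function(idx) {
    .ccaLambdas(Sxx, Syy, crossCov(idx), SxxInv, SyyInv)
  }
  list(n = n, lambdas = lambdas)
}

## Sequential Wilks statistic: Lambda_k = prod_{j >= k} (1 - lambda_j).
## Small values indicate association for variate k and beyond.
.wilksSeq <- function(lambda) rev(cumprod(rev(1 - lambda)))

.droppedMatrix <- function(x) {
  m <- cohortMatrix(x)
  sets <- unname(variableSets(x))
  am <- suppressWarnings(giniCovariance(x))
  keep <- !am@zeroVariance
  list(m = m[, keep, drop = FALSE], sets = sets[keep],
       dropped = colnames(m)[!keep])
}

#' Permutation test for canonical correlations
#'
#' Tests each canonical variate by randomly permuting the Y-block rows
#' against the X-block rows (whole rows, so within-set dependence and
#' missingness patterns are preserved under the null of between-set
#' independence), re-running the full pipeline (Gini covariance, CCA) for
#' each permutation, and comparing the sequential Wilks-type statistic
#' \eqn{\Lambda_k = \prod_{j \ge k} (1 - \lambda_j)} to its observed value.
#' P-values use the add-one rule `(exceedances + 1) / (nPerm + 1)` and are
#' therefore never exactly 0.  Results are reproducible given `seed`.
#'
#' @param x a [CohortTable-class].
#' @param nPerm number of permutations (>= 99; default 10000).
#' @param seed integer RNG seed.
#'
#' @return an [InferenceResult-class] (standard errors unset; see
#'   [resampleSE()] / [inferCCA()]).
#'
#' @details Permutation replicates that fail numerically (e.g. a pair left
#'   with fewer than 2 complete cases) are dropped and counted; more than 5%
#'   failures is an error.
#' @export
permutationTest <- function(x, nPerm = 10000, seed = 1) {
  if (nPerm < 99) stop("nPerm must be at least 99")
  dm <- .droppedMatrix(x)
  m <- dm$m; sets <- dm$sets
  X <- m[, sets == "X", drop = FALSE]
  Y <- m[, sets == "Y", drop = FALSE]
  mach <- .permMachine(X, Y)
  lamObs <- mach$lambdas(seq_len(mach$n))
  K <- length(lamObs)
  wObs <- .wilksSeq(lamObs)
  wPerm <- matrix(NA_real_, nPerm, K)
  nFailed <- 0L
  .withSeed(seed, function() {
    for (b in seq_len(nPerm)) {
      idx <- sample.int(mach$n)
      lam <- tryCatch(mach$lambdas(idx), error = function(e) NULL)
      if (is.null(lam)) nFailed <<- nFailed + 1L
      else wPerm[b, ] <<- .wilksSeq(lam)
    }
  })
  if (nFailed > 0.05 * nPerm)
    stop(sprintf("%d of %d permutation replicates failed to solve", nFailed, nPerm))
  wPerm <- wPerm[!is.na(wPerm[, 1L]), , drop = FALSE]
  nUsed <- nrow(wPerm)
  pv <- vapply(seq_len(K), function(k)
    (sum(wPerm[, k] <= wObs[k]) + 1) / (nUsed + 1), numeric(1))
  qs <- t(apply(wPerm, 2L, stats::quantile,
                probs = c(0.05, 0.25, 0.5, 0.75, 0.95)))
  rownames(qs) <- paste0("CV", seq_len(K))
  new("InferenceResult",
      rho = sqrt(lamObs), pValues = pv,
      standardErrors = rep(NA_real_, K),
      nPerm = as.integer(nPerm), nBoot = 0L, nFailed = nFailed,
      seed = as.integer(seed), statistic = "sequential Wilks lambda",
      seMethod = NA_character_, nullQuantiles = qs)
}

#' Resampling standard errors for canonical correlations
#'
#' Standard errors of the canonical correlations `rho_k`, by default from a
#' subject-level bootstrap (resampling rows with replacement and re-running
#' Gini covariance + CCA).  The spread of the permutation null distribution
#' is available as `method = "permutation"`, but note it describes the null
#' distribution of the statistic, not the sampling error of the estimate.
#'
#' @param x a [CohortTable-class].
#' @param nResample bootstrap replicates (default 1000).
#' @param seed integer RNG seed.
#' @param method `"bootstrap"` (default) or `"permutation"`.
#' @param nPerm permutations when `method = "permutation"`.
#'
#' @return named numeric vector of per-variate standard errors.
#'
#' @details Degenerate bootstrap resamples (a zero-variance column or an
#'   unsolvable pair) are re-drawn, capped at 10 retries per replicate;
#'   if still degenerate (possible when a very rare variable has only one
#'   or two present cases), the constant column(s) are dropped for that
#'   replicate — the solver's own zero-variance policy — and only a whole
#'   degenerate variable set is an error.
#' @export
resampleSE <- function(x, nResample = 1000, seed = 1,
                       method = c("bootstrap", "permutation"),
                       nPerm = 1000) {
  method <- match.arg(method)
  dm <- .droppedMatrix(x)
  m <- dm$m; sets <- dm$sets
  if (method == "permutation") {
    X <- m[, sets == "X", drop = FALSE]
    Y <- m[, sets == "Y", drop = FALSE]
    mach <- .permMachine(X, Y)
    K <- length(mach$lambdas(seq_len(mach$n)))
    rhoPerm <- matrix(NA_real_, nPerm, K)
    .withSeed(seed, function() {
      for (b in seq_len(nPerm)) {
        lam <- tryCatch(mach$lambdas(sample.int(mach$n)), error = function(e) NULL)
        if (!is.null(lam)) rhoPerm[b, ] <<- sqrt(lam)
      }
    })
    se <- apply(rhoPerm, 2L, stats::sd, na.rm = TRUE)
  } else {
    n <- nrow(m)
    K <- min(sum(sets == "X"), sum(sets == "Y"))
    rhoBoot <- matrix(NA_real_, nResample, K)
    .withSeed(seed, function() {
      for (b in seq_len(nResample)) {
        lam <- NULL
        for (try in seq_len(10L)) {
          idx <- sample.int(n, replace = TRUE)
          mb <- m[idx, , drop = FALSE]
          lam <- tryCatch({
            if (any(colSums(mb == 1L, na.rm = TRUE) == 0) ||
                any(colSums(mb == 0L, na.rm = TRUE) == 0))
              stop("degenerate resample: constant column")
            .fitLambdas(mb, sets)
          }, error = function(e) NULL)
          if (!is.null(lam)) break
        }
        if (is.null(lam)) {
          ## after 10 redraws, fall back to the solver's own zero-variance
          ## policy: drop the constant column(s) for this replicate (a very
          ## rare variable can vanish from a resample with non-negligible
          ## probability); trailing variates of the replicate stay NA
          keep <- colSums(mb == 1L, na.rm = TRUE) > 0 &
                  colSums(mb == 0L, na.rm = TRUE) > 0
          if (sum(sets[keep] == "X") < 1L || sum(sets[keep] == "Y") < 1L)
            stop("bootstrap replicate degenerate after 10 retries: ",
                 "an entire variable set is constant")
          lam <- .fitLambdas(mb[, keep, drop = FALSE], sets[keep])
        }
        rhoBoot[b, seq_along(lam)] <<- sqrt(lam)
      }
    })
    se <- apply(rhoBoot, 2L, stats::sd, na.rm = TRUE)
  }
  stats::setNames(se, paste0("CV", seq_along(se)))
}

#' Combined permutation + bootstrap inference
#'
#' Convenience wrapper running [permutationTest()] and [resampleSE()] and
#' returning a single [InferenceResult-class] with per-variate p-values and
#' standard errors.
#'
#' @param x a [CohortTable-class].
#' @param nPerm permutations (default 10000).
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed integer RNG seed (the bootstrap uses `seed + 1`).
#' @param seMethod `"bootstrap"` or `"permutation"`.
#' @return an [InferenceResult-class].
#' @export
inferCCA <- function(x, nPerm = 10000, nBoot = 1000, seed = 1,
                     seMethod = c("bootstrap", "permutation")) {
  seMethod <- match.arg(seMethod)
  res <- permutationTest(x, nPerm = nPerm, seed = seed)
  se <- resampleSE(x, nResample = nBoot, seed = seed + 1L,
                   method = seMethod, nPerm = nPerm)
  res@standardErrors <- unname(se)
  res@nBoot <- as.integer(if (seMethod == "bootstrap") nBoot else nPerm)
  res@seMethod <- seMethod
  validObject(res)
  res
}

#' @rdname inference-accessors
#' @export
setMethod("pValues", "InferenceResult", function(x) x@pValues)

#' @rdname inference-accessors
#' @export
setMethod("standardErrors", "InferenceResult", function(x) x@standardErrors)

setMethod("show", "InferenceResult", function(object) {
  K <- length(object@pValues)
  cat("InferenceResult:", K, "canonical variate(s),",
      object@nPerm, "permutations (seed", paste0(object@seed, ")\n"))
  df <- data.frame(
    rho = round(object@rho, 3),
    se = round(object@standardErrors, 3),
    p = signif(object@pValues, 3)
  )
  print(utils::head(df, 5L))
  if (K > 5L) cat("  ...\n")
  if (object@nFailed)
    cat("  dropped permutation replicates:", object@nFailed, "\n")
})
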