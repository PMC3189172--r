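## Symmetric eigenvalue clipping to a small positive floor
## (eps = 1e-8 * trace/dim).  Pairwise-deleted Gini matrices need not be
## positive semidefinite, and the CCA solution inverts the within-set
## blocks, so indefiniteness is repaired here (and logged), not at the
## association-estimation stage.
.psdClip <- function(S, tag) {
  S <- (S + t(S)) / 2
  eps <- 1e-8 * sum(diag(S)) / ncol(S)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= eps)
    return(list(S = S, log = character()))
  nClip <- sum(e$values < eps)
  S2 <- e$vectors %*% (pmax(e$values, eps) * t(e$vectors))
  dimnames(S2) <- dimnames(S)
  list(
    S = (S2 + t(S2)) / 2,
    log = sprintf("PSD repair of %s: clipped %d eigenvalue(s) (min %.3e) to %.3e",
                  tag, nClip, min(e$values), eps)
  )
}

## Squared canonical correlations from the covariance blocks, via the
## eigenvalue problem on the smaller side; returns min(p, q) values,
## decreasing, clamped to [0, 1].
.ccaLambdas <- function(Sxx, Syy, Sxy,
                        SxxInv = solve(Sxx), SyyInv = solve(Syy),
                        checkComplex = FALSE) {
  p <- nrow(Sxx); q <- nrow(Syy)
  M <- if (p <= q) {
    SxxInv %*% Sxy %*% SyyInv %*% t(Sxy)
  } else {
    SyyInv %*% t(Sxy) %*% SxxInv %*% Sxy
  }
  ev <- eigen(M, only.values = TRUE)$values
  if (checkComplex && is.complex(ev) &&
      max(abs(Im(ev))) > 1e-6 * (1 + max(abs(Re(ev)))))
    stop("numerical error: eigenvalues have a non-negligible imaginary part")
  ev <- sort(Re(ev), decreasing = TRUE)[seq_len(min(p, q))]
  pmin(pmax(ev, 0), 1)
}

#' Solve the canonical correlation problem on Gini association matrices
#'
#' Finds the `K = min(p, q)` pairs of canonical variates maximizing the
#' correlation \eqn{a'S_{xy}b / \sqrt{a'S_{xx}a \; b'S_{yy}b}} by solving
#' the eigenvalue problems
#' \eqn{(S_{xx}^{-1} S_{xy} S_{yy}^{-1} S_{yx} - \lambda I)a = 0} and
#' \eqn{(S_{yy}^{-1} S_{yx} S_{xx}^{-1} S_{xy} - \lambda I)b = 0}, whose
#' common nonzero eigenvalues \eqn{\lambda = \rho^2} are the squared
#' canonical correlations.  Weights are normalized to unit variate variance
#' (`a'S_xx a = 1`), loadings (structural coefficients), cross-loadings and
#' redundancy coefficients are derived, and each variate's sign is fixed so
#' the largest-|loading| X variable loads positively.
#'
#' Because pairwise-available-case estimation can make the joint matrix
#' indefinite, the matrix is repaired before inversion by symmetric
#' eigenvalue clipping to a floor of `1e-8 * trace/dim`; an optional ridge
#' `gamma` is added to the within-set diagonals.  All adjustments are
#' recorded in the `repairLog`.  Zero-variance variables are dropped with a
#' warning rather than failing the run.
#'
#' @param x an [AssociationMatrices-class] (see [giniCovariance()]).
#' @param ridge non-negative ridge added to the diagonal of `S_xx` and
#'   `S_yy` (default 0).
#' @param dropZeroVariance drop flagged constant variables (default `TRUE`).
#' @param ... unused.
#'
#' @return a [CanonicalSolution-class].
#'
#' @examples
#' ct <- generateCohort(encephalitisPreset(seed = 1))
#' sol <- solveCCA(giniCovariance(ct))
#' canonicalCorrelations(sol)[1:3]
#' @rdname solveCCA
#' @export
setMethod("solveCCA", "AssociationMatrices", function(x, ridge = 0,
                                                      dropZeroVariance = TRUE, ...) {
  sets <- x@sets
  keep <- rep(TRUE, length(sets))
  dropped <- character()
  if (any(x@zeroVariance)) {
    if (!dropZeroVariance)
      stop("zero-variance variable(s) present; set dropZeroVariance = TRUE ",
           "or prune them")
    keep <- !x@zeroVariance
    dropped <- colnames(x@V)[!keep]
    warning("dropping zero-variance variable(s) from CCA: ",
            paste(dropped, collapse = ", "))
  }
  V <- x@V[keep, keep, drop = FALSE]
  sets <- sets[keep]
  p <- sum(sets == "X"); q <- sum(sets == "Y")
  if (p < 1L || q < 1L)
    stop("both sets must retain at least one variable")

  repairLog <- x@repairLog
  rep1 <- .psdClip(V, "joint covariance matrix")
  V <- rep1$S
  repairLog <- c(repairLog, rep1$log)

  ix <- sets == "X"; iy <- sets == "Y"
  Sxx <- V[ix, ix, drop = FALSE]
  Syy <- V[iy, iy, drop = FALSE]
  Sxy <- V[ix, iy, drop = FALSE]
  if (ridge > 0) {
    Sxx <- Sxx + diag(ridge, p)
    Syy <- Syy + diag(ridge, q)
    repairLog <- c(repairLog, sprintf("ridge %.3e added to S_xx and S_yy diagonals", ridge))
  }
  SxxInv <- tryCatch(solve(Sxx), error = function(e)
    stop("S_xx is singular after repair; prune collinear X variables or use ridge > 0"))
  SyyInv <- tryCatch(solve(Syy), error = function(e)
    stop("S_yy is singular after repair; prune collinear Y variables or use ridge > 0"))

  K <- min(p, q)
  ## eigenvectors from the smaller side; the other side's weights follow
  ## from the stationarity relation b proportional to S_yy^-1 S_yx a.
  if (p <= q) {
    M <- SxxInv %*% Sxy %*% SyyInv %*% t(Sxy)
  } else {
    M <- SyyInv %*% t(Sxy) %*% SxxInv %*% Sxy
  }
  e <- eigen(M)
  if (is.complex(e$values) &&
      max(abs(Im(e$values))) > 1e-6 * (1 + max(abs(Re(e$values)))))
    stop("numerical error: complex eigenvalue residuals beyond tolerance")
  ord <- order(Re(e$values), decreasing = TRUE)[seq_len(K)]
  lambda <- pmin(pmax(Re(e$values)[ord], 0), 1)
  W <- Re(e$vectors[, ord, drop = FALSE])

  normalize <- function(w, S) {
    s <- sqrt(max(drop(crossprod(w, S %*% w)), 0))
    if (s < sqrt(.Machine$double.xmin)) NULL else w / s
  }
  A <- matrix(0, p, K); B <- matrix(0, q, K)
  for (k in seq_len(K)) {
    if (p <= q) {
      a <- normalize(W[, k], Sxx)
      b <- normalize(SyyInv %*% t(Sxy) %*% a, Syy)
      if (is.null(b)) b <- normalize(replace(numeric(q), 1L + (k - 1L) %% q, 1), Syy)
    } else {
      b <- normalize(W[, k], Syy)
      a <- normalize(SxxInv %*% Sxy %*% b, Sxx)
      if (is.null(a)) a <- normalize(replace(numeric(p), 1L + (k - 1L) %% p, 1), Sxx)
    }
    rhoK <- drop(crossprod(a, Sxy %*% b))
    if (rhoK < 0) b <- -b
    A[, k] <- a; B[, k] <- b
  }
  rho <- sqrt(lambda)

  sdx <- sqrt(diag(Sxx)); sdy <- sqrt(diag(Syy))
  loadingsX <- (Sxx %*% A) / sdx
  loadingsY <- (Syy %*% B) / sdy
  ## sign convention: dominant X variable loads positively on each variate
  for (k in seq_len(K)) {
    i <- which.max(abs(loadingsX[, k]))
    if (loadingsX[i, k] < 0) {
      A[, k] <- -A[, k]; B[, k] <- -B[, k]
      loadingsX[, k] <- -loadingsX[, k]; loadingsY[, k] <- -loadingsY[, k]
    }
  }
  crossX <- (Sxy %*% B) / sdx
  crossY <- (t(Sxy) %*% A) / sdy

  xn <- colnames(V)[ix]; yn <- colnames(V)[iy]
  cvn <- paste0("CV", seq_len(K))
  dimnames(A) <- list(xn, cvn); dimnames(B) <- list(yn, cvn)
  dimnames(loadingsX) <- list(xn, cvn); dimnames(crossX) <- list(xn, cvn)
  dimnames(loadingsY) <- list(yn, cvn); dimnames(crossY) <- list(yn, cvn)

  new("CanonicalSolution",
      K = as.integer(K), rho = rho, lambda = lambda, A = A, B = B,
      loadingsX = loadingsX, loadingsY = loadingsY,
      crossX = crossX, crossY = crossY,
      redundancyY = colMeans(loadingsY^2) * lambda,
      redundancyX = colMeans(loadingsX^2) * lambda,
      dropped = dropped, repairLog = repairLog)
})

#' @rdname solveCCA
#' @export
setMethod("solveCCA", "CohortTable", function(x, ridge = 0,
                                              dropZeroVariance = TRUE, ...) {
  solveCCA(giniCovariance(x), ridge = ridge,
           dropZeroVariance = dropZeroVariance, ...)
})

#' @rdname solution-accessors
#' @export
setMethod("canonicalCorrelations", "CanonicalSolution", function(x) x@rho)

#' @rdname solution-accessors
#' @export
setMethod("canonicalEigenvalues", "CanonicalSolution", function(x) x@lambda)

#' @rdname solution-accessors
#' @export
setMethod("canonicalWeights", "CanonicalSolution", function(x, set = c("X", "Y")) {
  if (match.arg(set) == "X") x@A else x@B
})

#' @rdname solution-accessors
#' @export
setMethod("canonicalLoadings", "CanonicalSolution", function(x, set = c("X", "Y")) {
  if (match.arg(set) == "X") x@loadingsX else x@loadingsY
})

#' @rdname solution-accessors
#' @export
setMethod("crossLoadings", "CanonicalSolution", function(x, set = c("X", "Y")) {
  if (match.arg(set) == "X") x@crossX else x@crossY
})

#' Redundancy coefficients
#'
#' Per-variate redundancy: the proportion of one set's total variance
#' explained by the other set's canonical variate, computed as the mean
#' squared loading on variate `k` times \eqn{\lambda_k = \rho_k^2}.  Always
#' in `[0, lambda_k]`, attaining the upper bound when every loading is 1.
#'
#' @param x a [CanonicalSolution-class].
#' @param of `"Y"` (default): variance of the Y set explained by the X
#'   variates; `"X"` for the converse.
#' @return numeric vector of length `K`.
#' @export
redundancyCoefficients <- function(x, of = c("Y", "X")) {
  if (match.arg(of) == "Y") x@redundancyY else x@redundancyX
}

setMethod("show", "CanonicalSolution", function(object) {
  cat("CanonicalSolution:", object@K, "canonical variate pair(s)\n")
  k <- min(object@K, 5L)
  cat("  rho:", paste(sprintf("%.3f", object@rho[seq_len(k)]), collapse = " "),
      if (object@K > k) "...\n" else "\n")
  if (length(object@dropped))
    cat("  dropped zero-variance variables:",
        paste(object@dropped, collapse = ", "), "\n")
  if (length(object@repairLog))
    cat("  repairs:", paste(object@repairLog, collapse = "; "), "\n")
})

#' Canonical variate scores for each subject
#'
#' Computes the subject-level scores \eqn{U = X_c A} and \eqn{V = Y_c B} on
#' 0/1 data centered at the per-variable available-case means (prevalences).
#' A subject missing any variable used by a side gets a missing score on
#' that side.  On complete data, `cor(U[, k], V[, k])` reproduces
#' `rho[k]`.
#'
#' @param x a [CohortTable-class].
#' @param solution a [CanonicalSolution-class] fitted to this cohort.
#' @return list with matrices `U` (n x K) and `V` (n x K).
#' @export
canonicalScores <- function(x, solution) {
  score <- function(m, W) {
    m <- m[, rownames(W), drop = FALSE]
    ctr <- sweep(m, 2L, colMeans(m, na.rm = TRUE))
    s <- ctr %*% W                       # NA rows propagate automatically
    rownames(s) <- subjectIds(x)
    s
  }
  list(U = score(cohortMatrix(x, "X"), solution@A),
       V = score(cohortMatrix(x, "Y"), solution@B))
}

#' Structural coefficients table
#'
#' Long-format table of canonical loadings (correlation of each variable
#' with its own set's variate), cross-loadings (with the opposite set's
#' variate), and the derived "percent of variation contributed"
#' (`100 * loading^2`) and its cross counterpart.  The cross-loading obeys
#' the identity `cross = rho_k * loading`.
#'
#' @param solution a [CanonicalSolution-class].
#' @param variates which variates to tabulate (default: all).
#' @return `data.frame` with columns `variate`, `variable`, `set`,
#'   `loading`, `percentContribution`, `crossLoading`, `percentCross`.
#' @seealso [loadingContributions()] for the bare arithmetic on a loading
#'   vector.
#' @export
structuralCoefficients <- function(solution, variates = seq_len(solution@K)) {
  out <- lapply(variates, function(k) {
    rbind(
      data.frame(variate = k, variable = rownames(solution@loadingsX),
                 set = "X", loading = solution@loadingsX[, k],
                 crossLoading = solution@crossX[, k]),
      data.frame(variate = k, variable = rownames(solution@loadingsY),
                 set = "Y", loading = solution@loadingsY[, k],
                 crossLoading = solution@crossY[, k])
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$percentContribution <- 100 * out$loading^2
  out$percentCross <- 100 * out$crossLoading^2
  out[, c("variate", "variable", "set", "loading", "percentContribution",
          "crossLoading", "percentCross")]
}

#' Percent-of-variation arithmetic on canonical loadings
#'
#' The squared loading times 100 is the percent of a canonical variate's
#' variation contributed by a variable; multiplying a loading by the
#' canonical correlation `rho` gives its cross-loading, whose square is the
#' percent of the *opposite* set's variate explained.  This helper applies
#' that arithmetic to any loading vector (e.g. published loadings).
#'
#' @param loadings numeric vector of canonical loadings, optionally named.
#' @param rho canonical correlation of the variate; if supplied,
#'   cross-loadings and cross percents are included.
#' @return `data.frame` with columns `loading`, `percentContribution` and,
#'   when `rho` is given, `crossLoading`, `percentCross`.
#' @examples
#' loadingContributions(c(age = 0.94, WCC = -0.52), rho = 0.71)
#' @export
loadingContributions <- function(loadings, rho = NULL) {
  out <- data.frame(loading = as.numeric(loadings),
                    percentContribution = 100 * as.numeric(loadings)^2)
  if (!is.null(names(loadings))) rownames(out) <- names(loadings)
  if (!is.null(rho)) {
    out$crossLoading <- rho * out$loading
    out$percentCross <- 100 * out$crossLoading^2
  }
  out
}
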