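#' Gini covariance of a pair of binary variables
#'
#' The Gini-index generalization of covariance for categorical data: with
#' the identity transformation, the covariance of variables \eqn{x_i} and
#' \eqn{x_j} over \eqn{m} subjects is the pairwise-difference double sum
#' \deqn{Q_{ij} = \frac{1}{2m^2} \sum_a \sum_b (x_{ia} - x_{ib})(x_{ja} - x_{jb}),}
#' which for 0/1 indicators equals the mean-centered product-moment
#' covariance with divisor \eqn{m} (population form); for \eqn{x = y} it is
#' the Gini variance \eqn{p(1 - p)}.  Subjects with a missing value in
#' either variable are excluded (pairwise-available-case analysis), and all
#' means use the retained subjects.
#'
#' @param x,y vectors of 0, 1 and `NA`, equal length.
#' @return scalar covariance.
#' @examples
#' giniPairCovariance(c(0, 1), c(0, 1))        # 0.25 = p(1-p), p = 0.5
#' giniPairCovariance(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 0
#' @seealso [giniCovariance()]
#' @export
giniPairCovariance <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  keep <- !(is.na(x) | is.na(y))
  m <- sum(keep)
  if (m < 2L)
    stop("undefined covariance: fewer than 2 complete cases for the pair")
  x <- x[keep]; y <- y[keep]
  mean(x * y) - mean(x) * mean(y)
}

## Entrywise pairwise-complete Gini covariance of all columns of Z
## (0/1/NA matrix), via indicator-matrix cross-products.  Returns the
## covariance matrix (divisor = pairwise m) and the pairwise counts.
.giniCovPairwise <- function(Z) {
  obs <- !is.na(Z)
  Z0 <- Z
  Z0[!obs] <- 0
  storage.mode(Z0) <- "double"
  storage.mode(obs) <- "double"
  N <- crossprod(obs)               # pairwise complete-case counts
  Sxy <- crossprod(Z0)              # sum of x_i x_j over joint-complete cases
  Sx <- crossprod(Z0, obs)          # Sx[i, j] = sum of x_i over cases complete for (i, j)
  V <- Sxy / N - (Sx / N) * (t(Sx) / N)
  V <- (V + t(V)) / 2               # exact symmetry against FP noise
  list(V = V, N = N)
}

#' Gini variance-covariance matrix of a cohort
#'
#' Fills the full \eqn{(p+q) \times (p+q)} Gini covariance matrix of a
#' binary cohort entrywise, each entry computed over the subjects complete
#' for that pair of variables (pairwise-available-case analysis), and
#' records the per-pair complete-case counts.  Constant (zero-variance)
#' variables are flagged with a warning; pairs with fewer than 2 complete
#' cases are an error.
#'
#' @param x a [CohortTable-class], or a subjects x variables 0/1/NA matrix.
#' @param sets for the matrix method: `"X"`/`"Y"` label per variable.
#' @param L orthogonal transformation applied to category indicators; only
#'   `"identity"` is supported (for binary variables the maximum over
#'   orthogonal transformations is attained at the identity).
#' @param ... passed between methods.
#'
#' @return an [AssociationMatrices-class] with `V` and `pairwiseN` filled
#'   (use [giniCorrelation()] for `R`).
#'
#' @examples
#' ct <- generateCohort(encephalitisPreset(seed = 1))
#' am <- giniCorrelation(giniCovariance(ct))
#' range(pairwiseN(am))
#' @rdname giniCovariance
#' @export
setMethod("giniCovariance", "CohortTable", function(x, L = "identity", ...) {
  giniCovariance(cohortMatrix(x), sets = variableSets(x), L = L)
})

#' @rdname giniCovariance
#' @export
setMethod("giniCovariance", "matrix", function(x, sets, L = "identity", ...) {
  if (!identical(L, "identity") && !identical(L, 1) && !identical(L, 1L))
    stop("only the identity transformation L is supported")
  if (nrow(x) < 2L) stop("at least 2 subjects are required")
  sets <- .normalizeSets(sets)
  pc <- .giniCovPairwise(x)
  tooFew <- which(pc$N < 2, arr.ind = TRUE)
  if (nrow(tooFew)) {
    i <- tooFew[1L, 1L]; j <- tooFew[1L, 2L]
    stop(sprintf(
      "pair ('%s', '%s') has fewer than 2 complete cases",
      colnames(x)[i], colnames(x)[j]))
  }
  V <- pc$V
  zero <- diag(V) <= 0
  diag(V)[diag(V) < 0] <- 0         # -0 from FP cancellation
  if (any(zero))
    warning("zero-variance variable(s): ",
            paste(colnames(x)[zero], collapse = ", "),
            " (off-diagonal correlations will be set to 0)")
  N <- pc$N
  storage.mode(N) <- "integer"
  new("AssociationMatrices",
      V = V, pairwiseN = N, sets = unname(sets),
      nSubjects = nrow(x), L = "identity",
      zeroVariance = unname(zero),
      repairLog = character())
})

#' Gini correlation matrix
#'
#' Fills the correlation matrix \eqn{R_{ij} = V_{ij} / \sqrt{V_{ii} V_{jj}}}
#' of an [AssociationMatrices-class].  The diagonal is exactly 1 for
#' variables with positive variance; rows/columns of flagged zero-variance
#' variables are set to 0 off-diagonal.
#'
#' @param x an [AssociationMatrices-class] with `V` computed, or a
#'   [CohortTable-class] (shorthand for
#'   `giniCorrelation(giniCovariance(x))`).
#' @param ... passed between methods.
#' @return the [AssociationMatrices-class] with slot `R` filled.
#' @rdname giniCorrelation
#' @export
setMethod("giniCorrelation", "AssociationMatrices", function(x, ...) {
  V <- x@V
  s <- sqrt(diag(V))
  s[s == 0] <- NA_real_
  R <- V / tcrossprod(s)
  R[is.na(R)] <- 0
  diag(R)[!is.na(s)] <- 1
  diag(R)[is.na(s)] <- 1            # conventional unit diagonal
  R[abs(R) > 1] <- sign(R[abs(R) > 1])   # clamp FP overshoot
  x@R <- R
  validObject(x)
  x
})

#' @rdname giniCorrelation
#' @export
setMethod("giniCorrelation", "CohortTable", function(x, ...) {
  giniCorrelation(giniCovariance(x), ...)
})

#' Construct AssociationMatrices from a covariance matrix
#'
#' Low-level constructor wrapping an externally supplied (e.g. population or
#' simulated) covariance matrix so it can be fed to [solveCCA()].
#'
#' @param V symmetric covariance matrix with variable names.
#' @param sets `"X"`/`"Y"` label per variable.
#' @param nSubjects optional sample size behind `V`.
#' @param pairwiseN optional per-pair complete-case counts (defaults to
#'   `nSubjects` everywhere).
#' @return an [AssociationMatrices-class].
#' @export
AssociationMatrices <- function(V, sets, nSubjects = NA_integer_,
                                pairwiseN = NULL) {
  sets <- .normalizeSets(sets)
  if (is.null(pairwiseN)) {
    pairwiseN <- matrix(as.integer(nSubjects), nrow(V), ncol(V),
                        dimnames = dimnames(V))
  }
  storage.mode(pairwiseN) <- "integer"
  new("AssociationMatrices",
      V = V, pairwiseN = pairwiseN, sets = unname(sets),
      nSubjects = as.integer(nSubjects), L = "identity",
      zeroVariance = diag(V) <= 0, repairLog = character())
}

#' @rdname association-accessors
#' @export
setMethod("giniV", "AssociationMatrices", function(x) x@V)

#' @rdname association-accessors
#' @export
setMethod("giniR", "AssociationMatrices", function(x) {
  if (!length(x@R)) stop("R not computed yet; call giniCorrelation() first")
  x@R
})

#' @rdname association-accessors
#' @export
setMethod("pairwiseN", "AssociationMatrices", function(x) x@pairwiseN)

#' @rdname association-accessors
#' @export
setMethod("Sxx", "AssociationMatrices", function(x) {
  i <- x@sets == "X"
  x@V[i, i, drop = FALSE]
})

#' @rdname association-accessors
#' @export
setMethod("Syy", "AssociationMatrices", function(x) {
  i <- x@sets == "Y"
  x@V[i, i, drop = FALSE]
})

#' @rdname association-accessors
#' @export
setMethod("Sxy", "AssociationMatrices", function(x) {
  x@V[x@sets == "X", x@sets == "Y", drop = FALSE]
})

#' @rdname set-accessors
#' @export
setMethod("variableSets", "AssociationMatrices", function(x) {
  stats::setNames(x@sets, colnames(x@V))
})

#' @rdname set-accessors
#' @export
setMethod("nSubjects", "AssociationMatrices", function(x) x@nSubjects)

setMethod("show", "AssociationMatrices", function(object) {
  d <- ncol(object@V)
  cat("AssociationMatrices:", d, "variables (",
      sum(object@sets == "X"), "X /", sum(object@sets == "Y"), "Y ),",
      "Gini covariance with L =", object@L, "\n")
  if (length(object@pairwiseN))
    cat("  pairwise complete-case counts:",
        min(object@pairwiseN), "-", max(object@pairwiseN), "\n")
  if (any(object@zeroVariance))
    cat("  zero-variance variables:", sum(object@zeroVariance), "\n")
  if (length(object@repairLog))
    cat("  repairs:", paste(object@repairLog, collapse = "; "), "\n")
})

#' Write association matrices as labeled CSV files
#'
#' Writes `V`, `R` (if computed) and the pairwise complete-case counts as
#' labeled square CSV matrices (heatmap-ready).
#'
#' @param x an [AssociationMatrices-class].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return paths of the files written, invisibly.
#' @export
writeAssociation <- function(x, dir, prefix = "gini") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(m, name) {
    p <- file.path(dir, paste0(prefix, "_", name, ".csv"))
    utils::write.csv(as.data.frame(m), p, row.names = TRUE)
    p
  }
  paths <- c(paths, wr(x@V, "covariance"))
  if (length(x@R)) paths <- c(paths, wr(x@R, "correlation"))
  paths <- c(paths, wr(x@pairwiseN, "pairwise_n"))
  invisible(paths)
}
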