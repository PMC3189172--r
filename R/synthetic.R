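## Latent correlation matrix implied by a SyntheticSpec: exchangeable
## within-set blocks and a rank-one between-set coupling whose latent
## canonical correlation is exactly rhoLatent along
## (directionX, directionY).
.latentSigma <- function(spec) {
  sets <- spec@sets
  p <- sum(sets == "X"); q <- sum(sets == "Y"); d <- p + q
  w <- spec@withinNoise
  Sxx <- matrix(w, p, p); diag(Sxx) <- 1
  Syy <- matrix(w, q, q); diag(Syy) <- 1
  dX <- spec@directionX / sqrt(sum(spec@directionX^2))
  dY <- spec@directionY / sqrt(sum(spec@directionY^2))
  u <- Sxx %*% dX
  v <- Syy %*% dY
  B <- spec@rhoLatent * tcrossprod(u, v) /
    sqrt(drop(crossprod(dX, u)) * drop(crossprod(dY, v)))
  Sigma <- matrix(0, d, d)
  ix <- which(sets == "X"); iy <- which(sets == "Y")
  Sigma[ix, ix] <- Sxx; Sigma[iy, iy] <- Syy
  Sigma[ix, iy] <- B; Sigma[iy, ix] <- t(B)
  dimnames(Sigma) <- list(names(spec@prevalences), names(spec@prevalences))
  Sigma
}

#' Construct a SyntheticSpec
#'
#' Parameters of the latent-threshold (Gaussian copula) binary-cohort
#' generator; see [SyntheticSpec-class] and [generateCohort()].
#'
#' @param prevalences named numeric vector in (0, 1): target `Pr(= 1)` per
#'   variable (the marginal prevalence is exact in expectation; thresholding
#'   a latent standard normal at `qnorm(1 - prevalence)`).
#' @param sets `"X"`/`"Y"` (or `"exposure_X"`/`"outcome_Y"`) per variable.
#' @param n number of subjects.
#' @param missingRates per-variable missing-completely-at-random rates in
#'   `[0, 1)`; recycled.
#' @param rhoLatent latent between-set canonical correlation in `[0, 1)`.
#'   Note the correlation observable on the binary scale is attenuated
#'   (phi < latent rho).
#' @param directionX,directionY vectors (one entry per X / Y variable)
#'   defining which variables carry the between-set signal; normalized
#'   internally; default: equal weight on every variable of the set.
#' @param withinNoise exchangeable within-set latent correlation in `[0, 1)`.
#' @param seed integer RNG seed; identical specs generate identical cohorts.
#' @return a validated [SyntheticSpec-class] (the implied latent correlation
#'   matrix is checked for positive semidefiniteness at construction).
#' @export
syntheticSpec <- function(prevalences, sets, n, missingRates = 0,
                          rhoLatent = 0, directionX = NULL, directionY = NULL,
                          withinNoise = 0, seed = 1) {
  if (is.null(names(prevalences)))
    names(prevalences) <- paste0("v", seq_along(prevalences))
  sets <- .normalizeSets(sets)
  if (!is.null(names(sets))) sets <- sets[names(prevalences)]
  missingRates <- rep_len(missingRates, length(prevalences))
  if (is.null(directionX)) directionX <- rep(1, sum(sets == "X"))
  if (is.null(directionY)) directionY <- rep(1, sum(sets == "Y"))
  if (sum(directionX^2) == 0 || sum(directionY^2) == 0)
    stop("direction vectors must be nonzero")
  new("SyntheticSpec",
      n = as.integer(n), prevalences = prevalences,
      missingRates = missingRates, sets = unname(sets),
      rhoLatent = rhoLatent,
      directionX = as.numeric(directionX), directionY = as.numeric(directionY),
      withinNoise = withinNoise, seed = as.integer(seed))
}

#' Generate a synthetic binary cohort
#'
#' Draws a latent multivariate normal with unit variances and the
#' correlation structure of the spec (exchangeable within-set correlation,
#' rank-one between-set coupling of canonical correlation `rhoLatent`),
#' thresholds each coordinate at the normal quantile of `1 - prevalence` to
#' produce 0/1 indicators, and applies MCAR missingness.  Deterministic
#' under the spec's seed (the caller's RNG state is left untouched).
#'
#' @param spec a [SyntheticSpec-class].
#' @param ... unused.
#' @return a [CohortTable-class] with `n` subjects.
#' @examples
#' spec <- syntheticSpec(c(a = 0.3, b = 0.6), sets = c("X", "Y"),
#'                       n = 500, rhoLatent = 0.5, seed = 7)
#' summarizeCohort(generateCohort(spec))
#' @rdname generateCohort
#' @export
setMethod("generateCohort", "SyntheticSpec", function(spec, ...) {
  validObject(spec)
  Sigma <- .latentSigma(spec)
  d <- ncol(Sigma)
  thr <- stats::qnorm(1 - spec@prevalences)
  .withSeed(spec@seed, function() {
    Z <- MASS::mvrnorm(spec@n, mu = rep(0, d), Sigma = Sigma)
    vals <- matrix(0L, spec@n, d, dimnames = list(NULL, colnames(Sigma)))
    vals[Z > matrix(thr, spec@n, d, byrow = TRUE)] <- 1L
    if (any(spec@missingRates > 0)) {
      miss <- matrix(stats::runif(spec@n * d), spec@n, d) <
        matrix(spec@missingRates, spec@n, d, byrow = TRUE)
      vals[miss] <- NA_integer_
    }
    CohortTable(vals, sets = spec@sets)
  })
})

#' Copy a SyntheticSpec with a new seed
#'
#' @param spec a [SyntheticSpec-class].
#' @param seed new integer seed.
#' @return the modified spec.
#' @export
reseedSpec <- function(spec, seed) {
  spec@seed <- as.integer(seed)
  spec
}

#' @rdname set-accessors
#' @export
setMethod("variableSets", "SyntheticSpec", function(x) {
  stats::setNames(x@sets, names(x@prevalences))
})

#' @rdname set-accessors
#' @export
setMethod("nSubjects", "SyntheticSpec", function(x) x@n)

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@n, "subjects,",
      sum(object@sets == "X"), "X /", sum(object@sets == "Y"), "Y variables\n")
  cat(sprintf("  latent canonical correlation %.2f, within-set correlation %.2f, seed %d\n",
              object@rhoLatent, object@withinNoise, object@seed))
  cat(sprintf("  prevalences %.3f-%.3f, missing rates %.3f-%.3f\n",
              min(object@prevalences), max(object@prevalences),
              min(object@missingRates), max(object@missingRates)))
})
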