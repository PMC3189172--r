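#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.SET_LEVELS <- c("X", "Y")

## Map user-facing set labels onto the internal "X"/"Y" coding.
.normalizeSets <- function(sets) {
  map <- c(
    X = "X", exposure_X = "X", exposure = "X", x = "X",
    Y = "Y", outcome_Y = "Y", outcome = "Y", y = "Y"
  )
  out <- unname(map[as.character(sets)])
  if (anyNA(out)) {
    bad <- unique(as.character(sets)[is.na(out)])
    stop("unknown set label(s): ", paste(bad, collapse = ", "),
         " (use 'exposure_X'/'X' or 'outcome_Y'/'Y')")
  }
  names(out) <- names(sets)
  out
}

#' CohortTable: subjects by binary clinical variables
#'
#' A `CohortTable` holds a cohort of subjects measured on binary (0/1,
#' possibly missing) clinical indicators, each variable assigned to either the
#' exposure/demographic set (`"X"`) or the symptom/diagnostic outcome set
#' (`"Y"`).  It extends [SummarizedExperiment::SummarizedExperiment] with
#' variables as rows (assay `"status"`) and subjects as columns; the set
#' assignment lives in `rowData(x)$set`.
#'
#' @slot .  See [SummarizedExperiment::SummarizedExperiment].
#'
#' @seealso [CohortTable()], [readCohort()], [summarizeCohort()],
#'   [giniCovariance()]
#' @export
setClass("CohortTable", contains = "SummarizedExperiment")

setValidity("CohortTable", function(object) {
  msg <- character()
  if (!"status" %in% assayNames(object))
    return("assay 'status' is required")
  a <- assay(object, "status")
  if (!all(a[!is.na(a)] %in% c(0L, 1L)))
    msg <- c(msg, "every cell must be 0, 1 or NA")
  sets <- rowData(object)$set
  if (is.null(sets) || !all(sets %in% .SET_LEVELS)) {
    msg <- c(msg, "rowData(object)$set must assign every variable to 'X' or 'Y'")
  } else {
    if (sum(sets == "X") < 1L) msg <- c(msg, "at least one X (exposure) variable is required")
    if (sum(sets == "Y") < 1L) msg <- c(msg, "at least one Y (outcome) variable is required")
  }
  vn <- rownames(object)
  if (is.null(vn) || anyDuplicated(vn))
    msg <- c(msg, "variable names must be present and unique")
  if (length(msg)) msg else TRUE
})

#' AssociationMatrices: Gini covariance/correlation for binary variables
#'
#' Container for the Gini-index variance-covariance matrix `V`, the derived
#' correlation matrix `R`, the per-pair complete-case counts used under
#' pairwise-available-case analysis, the X/Y set assignment (giving the
#' within-set blocks `S_xx`, `S_yy` and between-set block `S_xy`), and a log
#' of any positive-semidefinite repair applied downstream.
#'
#' @slot V numeric matrix, Gini variance-covariance matrix (divisor `m`).
#' @slot R numeric matrix, correlation matrix `R_ij = V_ij / sqrt(V_ii V_jj)`;
#'   a 0 x 0 matrix until [giniCorrelation()] is called.
#' @slot pairwiseN integer matrix of per-pair complete-case counts.
#' @slot sets character vector, `"X"` or `"Y"` per variable.
#' @slot nSubjects integer, cohort size the matrices were computed from.
#' @slot L character, the orthogonal transformation used (only `"identity"`
#'   is supported: for binary indicators the max over transformations is
#'   attained at the identity).
#' @slot zeroVariance logical vector flagging constant variables.
#' @slot repairLog character vector of adjustments applied.
#'
#' @seealso [giniCovariance()], [giniCorrelation()], [Sxx()], [solveCCA()]
#' @export
setClass("AssociationMatrices",
  slots = c(
    V = "matrix", R = "matrix", pairwiseN = "matrix",
    sets = "character", nSubjects = "integer", L = "character",
    zeroVariance = "logical", repairLog = "character"
  ),
  prototype = list(
    R = matrix(numeric(), 0L, 0L), L = "identity",
    nSubjects = NA_integer_, zeroVariance = logical(), repairLog = character()
  )
)

setValidity("AssociationMatrices", function(object) {
  msg <- character()
  V <- object@V
  d <- ncol(V)
  if (nrow(V) != d) msg <- c(msg, "V must be square")
  if (length(object@sets) != d)
    msg <- c(msg, "sets must have one entry per variable")
  if (!all(object@sets %in% .SET_LEVELS))
    msg <- c(msg, "sets must be 'X' or 'Y'")
  if (d && max(abs(V - t(V))) > 1e-8 * (1 + max(abs(V))))
    msg <- c(msg, "V must be symmetric")
  if (d && any(diag(V) < -1e-12))
    msg <- c(msg, "diagonal of V must be non-negative")
  if (!identical(dim(object@pairwiseN), dim(V)))
    msg <- c(msg, "pairwiseN must match V in shape")
  R <- object@R
  if (length(R)) {
    if (!identical(dim(R), dim(V)))
      msg <- c(msg, "R must match V in shape")
    else if (any(abs(R[!is.na(R)]) > 1 + 1e-8))
      msg <- c(msg, "|R_ij| must not exceed 1")
  }
  if (length(msg)) msg else TRUE
})

#' CanonicalSolution: canonical correlations, weights and loadings
#'
#' Result of [solveCCA()]: `K = min(p, q)` canonical variate pairs in
#' decreasing order of canonical correlation, with the weight vectors
#' (normalized to unit variance of each variate), structural coefficients
#' (loadings), cross-loadings and redundancy coefficients.
#'
#' @slot K integer, number of variate pairs, `min(p, q)`.
#' @slot rho numeric, canonical correlations (decreasing, in `[0, 1]`).
#' @slot lambda numeric, squared canonical correlations (eigenvalues).
#' @slot A,B numeric matrices (`p x K`, `q x K`) of canonical weights,
#'   normalized so `a' S_xx a = 1` and `b' S_yy b = 1`.
#' @slot loadingsX,loadingsY correlations of each variable with its own
#'   set's variates.
#' @slot crossX,crossY correlations of each variable with the opposite
#'   set's variates (`cross = rho * loading`).
#' @slot redundancyY,redundancyX per-variate redundancy coefficients
#'   (variance of one set explained by the other set's variate).
#' @slot dropped character, zero-variance variables excluded from the fit.
#' @slot repairLog character, PSD repairs and ridge adjustments applied.
#'
#' @seealso [solveCCA()], [canonicalCorrelations()], [canonicalLoadings()],
#'   [redundancyCoefficients()], [structuralCoefficients()]
#' @export
setClass("CanonicalSolution",
  slots = c(
    K = "integer", rho = "numeric", lambda = "numeric",
    A = "matrix", B = "matrix",
    loadingsX = "matrix", loadingsY = "matrix",
    crossX = "matrix", crossY = "matrix",
    redundancyY = "numeric", redundancyX = "numeric",
    dropped = "character", repairLog = "character"
  )
)

setValidity("CanonicalSolution", function(object) {
  msg <- character()
  K <- object@K
  if (length(object@rho) != K || length(object@lambda) != K)
    msg <- c(msg, "rho and lambda must have length K")
  if (K && (any(object@rho < -1e-10) || any(object@rho > 1 + 1e-8)))
    msg <- c(msg, "canonical correlations must lie in [0, 1]")
  if (K > 1 && any(diff(object@rho) > 1e-10))
    msg <- c(msg, "canonical correlations must be in decreasing order")
  if (ncol(object@A) != K || ncol(object@B) != K)
    msg <- c(msg, "A and B must have K columns")
  if (length(msg)) msg else TRUE
})

#' InferenceResult: permutation p-values and resampling standard errors
#'
#' Per-variate nonparametric inference for a canonical correlation analysis:
#' p-values from row permutation of the Y block (sequential Wilks-type
#' statistic, add-one rule) and standard errors of the canonical correlations
#' from subject-level bootstrap (or, optionally, the permutation spread).
#'
#' @slot rho numeric, observed canonical correlations.
#' @slot pValues numeric, per-variate permutation p-values in `(0, 1]`.
#' @slot standardErrors numeric, per-variate standard errors (`NA` until
#'   [resampleSE()] has been run, e.g. by [inferCCA()]).
#' @slot nPerm,nBoot integer, resampling sizes.
#' @slot nFailed integer, permutation replicates dropped for numerical failure.
#' @slot seed integer, RNG seed the results are reproducible under.
#' @slot statistic character, name of the permutation statistic.
#' @slot seMethod character, `"bootstrap"` or `"permutation"`.
#' @slot nullQuantiles matrix of per-variate quantiles of the permuted
#'   statistic.
#'
#' @seealso [permutationTest()], [resampleSE()], [inferCCA()]
#' @export
setClass("InferenceResult",
  slots = c(
    rho = "numeric", pValues = "numeric", standardErrors = "numeric",
    nPerm = "integer", nBoot = "integer", nFailed = "integer",
    seed = "integer", statistic = "character", seMethod = "character",
    nullQuantiles = "matrix"
  ),
  prototype = list(
    standardErrors = numeric(), nBoot = 0L, nFailed = 0L,
    statistic = "sequential Wilks lambda", seMethod = NA_character_
  )
)

setValidity("InferenceResult", function(object) {
  msg <- character()
  p <- object@pValues
  if (length(p) && (any(p <= 0) || any(p > 1)))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (length(object@rho) && length(p) && length(p) != length(object@rho))
    msg <- c(msg, "pValues must match rho in length")
  if (length(msg)) msg else TRUE
})

#' SyntheticSpec: latent-threshold generator parameters
#'
#' Parameters of the latent-threshold (Gaussian copula) generator for binary
#' cohorts: a latent multivariate normal with unit variances, exchangeable
#' within-set correlation `withinNoise`, and a rank-one between-set coupling
#' of canonical correlation `rhoLatent` along the unit directions
#' `directionX`/`directionY`, is thresholded per variable at the normal
#' quantile of `1 - prevalence`, then missing-completely-at-random masking is
#' applied.  Thresholding attenuates correlation, so the canonical
#' correlation observable on the binary scale is smaller than `rhoLatent`.
#'
#' @slot n integer, number of subjects.
#' @slot prevalences named numeric in (0, 1), target `Pr(variable = 1)`.
#' @slot missingRates numeric in `[0, 1)`, per-variable MCAR rates.
#' @slot sets character, `"X"`/`"Y"` per variable.
#' @slot rhoLatent numeric in `[0, 1)`, latent between-set canonical
#'   correlation.
#' @slot directionX,directionY numeric unit vectors carrying the signal.
#' @slot withinNoise numeric in `[0, 1)`, exchangeable within-set latent
#'   correlation.
#' @slot seed integer RNG seed; identical specs generate identical cohorts.
#'
#' @seealso [syntheticSpec()], [generateCohort()], [encephalitisPreset()]
#' @export
setClass("SyntheticSpec",
  slots = c(
    n = "integer", prevalences = "numeric", missingRates = "numeric",
    sets = "character", rhoLatent = "numeric",
    directionX = "numeric", directionY = "numeric",
    withinNoise = "numeric", seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  d <- length(object@prevalences)
  if (length(object@sets) != d || length(object@missingRates) != d)
    msg <- c(msg, "prevalences, missingRates and sets must have equal length")
  if (any(object@prevalences <= 0) || any(object@prevalences >= 1))
    msg <- c(msg, "prevalences must lie strictly in (0, 1)")
  if (any(object@missingRates < 0) || any(object@missingRates >= 1))
    msg <- c(msg, "missingRates must lie in [0, 1)")
  if (object@rhoLatent < 0 || object@rhoLatent >= 1)
    msg <- c(msg, "rhoLatent must lie in [0, 1)")
  if (object@withinNoise < 0 || object@withinNoise >= 1)
    msg <- c(msg, "withinNoise must lie in [0, 1)")
  if (!all(object@sets %in% .SET_LEVELS))
    msg <- c(msg, "sets must be 'X' or 'Y'")
  if (length(object@directionX) != sum(object@sets == "X"))
    msg <- c(msg, "directionX must have one entry per X variable")
  if (length(object@directionY) != sum(object@sets == "Y"))
    msg <- c(msg, "directionY must have one entry per Y variable")
  if (object@n < 2L) msg <- c(msg, "n must be at least 2")
  if (length(msg)) return(msg)
  ## latent correlation matrix must be PSD before any sampling happens
  ev <- tryCatch(
    min(eigen(.latentSigma(object), symmetric = TRUE, only.values = TRUE)$values),
    error = function(e) -Inf
  )
  if (ev < -1e-8)
    return("requested latent correlation structure is not positive semidefinite")
  TRUE
})
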