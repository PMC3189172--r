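#' @rdname giniCovariance
#' @export
setGeneric("giniCovariance", function(x, ...) standardGeneric("giniCovariance"))

#' @rdname giniCorrelation
#' @export
setGeneric("giniCorrelation", function(x, ...) standardGeneric("giniCorrelation"))

#' @rdname solveCCA
#' @export
setGeneric("solveCCA", function(x, ...) standardGeneric("solveCCA"))

#' @rdname summarizeCohort
#' @export
setGeneric("summarizeCohort", function(x, ...) standardGeneric("summarizeCohort"))

#' @rdname generateCohort
#' @export
setGeneric("generateCohort", function(spec, ...) standardGeneric("generateCohort"))

#' Accessors for association matrices
#'
#' `Sxx()`, `Syy()` and `Sxy()` return the within-set and between-set blocks
#' of the Gini variance-covariance matrix; `pairwiseN()` the per-pair
#' complete-case counts; `giniV()` and `giniR()` the full covariance and
#' correlation matrices.
#'
#' @param x an [AssociationMatrices-class] object.
#' @return a numeric (or integer, for `pairwiseN`) matrix.
#' @seealso [giniCovariance()]
#' @rdname association-accessors
#' @export
setGeneric("Sxx", function(x) standardGeneric("Sxx"))

#' @rdname association-accessors
#' @export
setGeneric("Syy", function(x) standardGeneric("Syy"))

#' @rdname association-accessors
#' @export
setGeneric("Sxy", function(x) standardGeneric("Sxy"))

#' @rdname association-accessors
#' @export
setGeneric("pairwiseN", function(x) standardGeneric("pairwiseN"))

#' @rdname association-accessors
#' @export
setGeneric("giniV", function(x) standardGeneric("giniV"))

#' @rdname association-accessors
#' @export
setGeneric("giniR", function(x) standardGeneric("giniR"))

#' Accessors shared by cohort-derived objects
#'
#' `variableSets()` returns the named `"X"`/`"Y"` assignment of every
#' variable; `nSubjects()` the number of subjects.
#'
#' @param x a [CohortTable-class], [AssociationMatrices-class] or
#'   [SyntheticSpec-class] object.
#' @rdname set-accessors
#' @export
setGeneric("variableSets", function(x) standardGeneric("variableSets"))

#' @rdname set-accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' Accessors for canonical solutions
#'
#' `canonicalCorrelations()` returns the vector `rho` of canonical
#' correlations (decreasing); `canonicalEigenvalues()` the squared
#' correlations `lambda`; `canonicalWeights()` the weight matrix of one set;
#' `canonicalLoadings()` and `crossLoadings()` the structural coefficients
#' with the own-set and opposite-set variates.
#'
#' @param x a [CanonicalSolution-class] object.
#' @param set `"X"` or `"Y"`: which variable set the coefficients refer to.
#' @rdname solution-accessors
#' @export
setGeneric("canonicalCorrelations", function(x) standardGeneric("canonicalCorrelations"))

#' @rdname solution-accessors
#' @export
setGeneric("canonicalEigenvalues", function(x) standardGeneric("canonicalEigenvalues"))

#' @rdname solution-accessors
#' @export
setGeneric("canonicalWeights", function(x, set = c("X", "Y")) standardGeneric("canonicalWeights"))

#' @rdname solution-accessors
#' @export
setGeneric("canonicalLoadings", function(x, set = c("X", "Y")) standardGeneric("canonicalLoadings"))

#' @rdname solution-accessors
#' @export
setGeneric("crossLoadings", function(x, set = c("X", "Y")) standardGeneric("crossLoadings"))

#' Accessors for inference results
#'
#' @param x an [InferenceResult-class] object.
#' @rdname inference-accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname inference-accessors
#' @export
setGeneric("standardErrors", function(x) standardGeneric("standardErrors"))
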