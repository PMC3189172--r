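#' Construct a CohortTable
#'
#' Builds a validated [CohortTable-class] from a subjects x variables matrix
#' of 0/1 indicators (missing values as `NA`) and a set assignment mapping
#' every variable to the exposure set `X` or the outcome set `Y`.
#'
#' @param values numeric/integer matrix or data.frame, subjects in rows,
#'   variables in columns; entries 0, 1 or `NA`.  Column names are the
#'   variable names.
#' @param sets character vector with one label per variable (in column order,
#'   or named by variable), each `"exposure_X"`/`"X"` or `"outcome_Y"`/`"Y"`.
#' @param subjectIds optional subject identifiers (default: row names of
#'   `values`, or `subj1..subjN`).
#'
#' @return a [CohortTable-class].
#'
#' @examples
#' m <- cbind(age10 = c(1, 0, 1), fever = c(1, 1, 0))
#' ct <- CohortTable(m, sets = c(age10 = "exposure_X", fever = "outcome_Y"))
#' nSubjects(ct)
#' variableSets(ct)
#' @export
CohortTable <- function(values, sets, subjectIds = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("'values' must have column (variable) names")
  if (!is.numeric(values) && !is.logical(values))
    stop("'values' must be numeric 0/1 (or NA)")
  storage.mode(values) <- "integer"
  sets <- .normalizeSets(sets)
  if (!is.null(names(sets))) {
    missingVars <- setdiff(colnames(values), names(sets))
    if (length(missingVars))
      stop("no set assignment for variable(s): ",
           paste(missingVars, collapse = ", "))
    extraVars <- setdiff(names(sets), colnames(values))
    if (length(extraVars))
      stop("set assignment names unknown variable(s): ",
           paste(extraVars, collapse = ", "))
    sets <- sets[colnames(values)]
  } else if (length(sets) != ncol(values)) {
    stop("'sets' must have one label per variable")
  }
  if (is.null(subjectIds)) subjectIds <- rownames(values)
  if (is.null(subjectIds)) subjectIds <- paste0("subj", seq_len(nrow(values)))
  a <- t(values)
  colnames(a) <- subjectIds
  se <- SummarizedExperiment(
    assays = list(status = a),
    rowData = DataFrame(set = unname(sets), row.names = colnames(values))
  )
  new("CohortTable", se)
}

#' @rdname set-accessors
#' @export
setMethod("variableSets", "CohortTable", function(x) {
  stats::setNames(rowData(x)$set, rownames(x))
})

#' @rdname set-accessors
#' @export
setMethod("nSubjects", "CohortTable", function(x) ncol(x))

#' Extract the subjects x variables matrix of a cohort
#'
#' @param x a [CohortTable-class].
#' @param set `"all"`, `"X"` or `"Y"`: all variables or one block.
#' @return integer matrix, subjects in rows, variables in columns, `NA` for
#'   missing.
#' @export
cohortMatrix <- function(x, set = c("all", "X", "Y")) {
  set <- match.arg(set)
  m <- t(assay(x, "status"))
  if (set != "all") m <- m[, variableSets(x) == set, drop = FALSE]
  m
}

#' Subject identifiers of a cohort
#' @param x a [CohortTable-class].
#' @export
subjectIds <- function(x) colnames(x)

setMethod("show", "CohortTable", function(object) {
  sets <- variableSets(object)
  a <- assay(object, "status")
  cat("CohortTable:", ncol(object), "subjects,",
      sum(sets == "X"), "exposure (X) and",
      sum(sets == "Y"), "outcome (Y) variables\n")
  cat(sprintf("  missing cells: %.1f%%\n", 100 * mean(is.na(a))))
})

#' Dichotomize a numeric column against a threshold
#'
#' Maps a numeric vector to 0/1 by a threshold rule: values on the
#' `codeOneWhen` side of `threshold` (inclusivity follows `operator`
#' exactly) become 1, the rest 0; missing values stay missing.  E.g. the
#' rule "age <= 10" puts age 10 in the coded-1 (young children) group.
#'
#' @param column numeric vector, possibly with `NA`.
#' @param threshold finite numeric cutoff (same units as `column`,
#'   e.g. years or days).
#' @param operator one of `"<="`, `"<"`, `">="`, `">"`: the comparison whose
#'   TRUE side is coded 1.
#'
#' @return integer vector of 0, 1 and `NA`.
#'
#' @examples
#' dichotomize(c(9, 10, 11, NA), 10, "<=")  # 1 1 0 NA
#' dichotomize(c(50, 51), 50, "<=")         # 1 0
#' @export
dichotomize <- function(column, threshold, operator = c("<=", "<", ">=", ">")) {
  operator <- match.arg(operator)
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("'threshold' must be a single finite number")
  if (!is.numeric(column)) {
    suppressWarnings(num <- as.numeric(column))
    if (any(is.na(num) & !is.na(column)))
      stop("non-numeric entry in column to dichotomize")
    column <- num
  }
  out <- switch(operator,
    "<=" = column <= threshold,
    "<"  = column <  threshold,
    ">=" = column >= threshold,
    ">"  = column >  threshold
  )
  as.integer(out)
}

.readConfig <- function(config) {
  if (is.character(config) && length(config) == 1L && file.exists(config)) {
    config <- yaml::read_yaml(config)
  }
  if (is.list(config) && !is.null(config$variables)) {
    rules <- config$rules
    config <- config$variables
  } else {
    rules <- NULL
  }
  sets <- unlist(config)
  list(sets = .normalizeSets(sets), rules = rules)
}

#' Read a cohort from CSV
#'
#' Reads a subjects x variables CSV (header row of variable names, one row
#' per subject) of binary indicators into a [CohortTable-class].  Cells
#' equal to `missingToken` become missing; any other cell not `0` or `1` is
#' rejected, unless a dichotomization rule is supplied for that variable, in
#' which case the column is read as numeric and thresholded first.
#'
#' @param csvPath path to a CSV file (RFC-4180, UTF-8).
#' @param config set assignment: a named character vector/list mapping every
#'   variable to `"exposure_X"` or `"outcome_Y"`, or the path of a YAML file
#'   (either a flat `variable: set` map, or a map with keys `variables:` and
#'   optionally `rules:`; a rule is `variable: {threshold: 10, operator: "<="}`).
#' @param missingToken string marking missing cells (default `"NA"`; empty
#'   cells are always treated as missing).
#' @param rules optional named list of dichotomization rules,
#'   `list(age = list(threshold = 10, operator = "<="))`; overrides rules
#'   from a YAML config.
#'
#' @return a validated [CohortTable-class].
#'
#' @seealso [writeCohort()], [dichotomize()]
#' @export
readCohort <- function(csvPath, config, missingToken = "NA", rules = NULL) {
  cfg <- .readConfig(config)
  if (is.null(rules)) rules <- cfg$rules
  raw <- utils::read.csv(csvPath, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  if (!ncol(raw)) stop("CSV has no columns")
  vars <- colnames(raw)
  unknown <- setdiff(vars, names(cfg$sets))
  if (length(unknown))
    stop("configuration error: variable(s) not in config: ",
         paste(unknown, collapse = ", "))
  vals <- matrix(NA_integer_, nrow(raw), length(vars),
                 dimnames = list(NULL, vars))
  for (v in vars) {
    cell <- raw[[v]]
    cell[cell == missingToken | cell == ""] <- NA_character_
    if (!is.null(rules[[v]])) {
      r <- rules[[v]]
      vals[, v] <- dichotomize(cell, r$threshold,
                               if (is.null(r$operator)) "<=" else r$operator)
    } else {
      bad <- which(!is.na(cell) & !cell %in% c("0", "1"))
      if (length(bad))
        stop(sprintf(
          "parse error: cell '%s' at row %d, column '%s' is not 0, 1 or '%s'",
          cell[bad[1L]], bad[1L], v, missingToken))
      vals[, v] <- as.integer(cell)
    }
  }
  CohortTable(vals, sets = cfg$sets[vars])
}

#' Write a cohort to CSV
#'
#' Inverse of [readCohort()]: writes the subjects x variables 0/1 table with
#' missing cells encoded as `missingToken`.  A `readCohort()` of the written
#' file (with the same config) round-trips to an identical table.
#'
#' @param x a [CohortTable-class].
#' @param csvPath output path.
#' @param missingToken string to write for missing cells.
#' @return `csvPath`, invisibly.
#' @export
writeCohort <- function(x, csvPath, missingToken = "NA") {
  m <- cohortMatrix(x)
  utils::write.csv(as.data.frame(m), csvPath, row.names = FALSE,
                   na = missingToken, quote = FALSE)
  invisible(csvPath)
}

#' Per-variable descriptive summary of a cohort
#'
#' Counts of present (1), absent (0) and missing per variable, with percents
#' of the full cohort size `n` (one-decimal rounding; present + absent +
#' missing percents sum to 100 up to rounding) and, separately, the percent
#' present among non-missing subjects — the convention used when a
#' diagnostic is only measured on a subset (e.g. an EEG performed on 120 of
#' 208 patients, abnormal in 100, is 48.1% of the cohort but 83.3% of those
#' measured).
#'
#' @param x a [CohortTable-class].
#' @return a `data.frame` with columns `variable`, `set`, `present`,
#'   `absent`, `missing`, `pctPresent`, `pctAbsent`, `pctMissing`
#'   (denominator `n`) and `pctPresentObserved` (denominator non-missing;
#'   `NA` when every value is missing).
#'
#' @rdname summarizeCohort
#' @export
setMethod("summarizeCohort", "CohortTable", function(x) {
  m <- cohortMatrix(x)
  n <- nrow(m)
  present <- colSums(m == 1L, na.rm = TRUE)
  absent <- colSums(m == 0L, na.rm = TRUE)
  miss <- colSums(is.na(m))
  observed <- present + absent
  data.frame(
    variable = colnames(m),
    set = unname(variableSets(x)),
    present = unname(present),
    absent = unname(absent),
    missing = unname(miss),
    pctPresent = round(100 * unname(present) / n, 1),
    pctAbsent = round(100 * unname(absent) / n, 1),
    pctMissing = round(100 * unname(miss) / n, 1),
    pctPresentObserved = ifelse(observed > 0,
                                round(100 * unname(present) / unname(observed), 1),
                                NA_real_),
    row.names = NULL
  )
})
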