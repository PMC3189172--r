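`%||%` <- function(a, b) if (is.null(a)) b else a

.fingerReport <- function(solution, inference, summary, topN = 10L) {
  ln <- character()
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("Canonical correlation analysis of binary clinical variables")
  add("===========================================================")
  add("%d exposure/demographic (X) and %d symptom/diagnostic (Y) variables; %d canonical variates.",
      nrow(solution@A), nrow(solution@B), solution@K)
  add("")
  add("First canonical variate: rho = %.2f, se = %.2f, p = %.3g (%d permutations)",
      solution@rho[1L], inference@standardErrors[1L], inference@pValues[1L],
      inference@nPerm)
  add("")
  bar <- function(v) strrep("#", round(40 * min(abs(v), 1)))
  for (set in c("X", "Y")) {
    L <- canonicalLoadings(solution, set)[, 1L]
    ord <- order(abs(L), decreasing = TRUE)[seq_len(min(topN, length(L)))]
    add("Top %s-set variables by |loading| (first variate):", set)
    for (i in ord)
      add("  %-24s %6.2f (%2.0f%%) %s", names(L)[i], L[i], 100 * L[i]^2, bar(L[i]))
    add("")
  }
  add("Redundancy (%% of Y-set variance explained by X variates 1..3): %s",
      paste(sprintf("%.0f%%", 100 * utils::head(solution@redundancyY, 3L)),
            collapse = ", "))
  ln
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: (optionally generate, then) summarize the
#' cohort, compute the Gini covariance/correlation matrices with
#' pairwise-available-case handling, solve the canonical correlation
#' problem, run permutation significance tests and bootstrap standard
#' errors, and write all artifacts to `outDir`:
#' `descriptives.csv`, `gini_covariance.csv`, `gini_correlation.csv`,
#' `gini_pairwise_n.csv`, `loadings.csv` (all variates),
#' `canonical_correlations.csv` (variate, rho, se, p-value), a ranked
#' text `report.txt` for the first canonical variate, and a
#' `manifest.yaml` recording versions, seed and any PSD repairs.
#' Every stochastic step is driven by `seed`, so a rerun with the same
#' inputs is byte-identical.
#'
#' @param cohort a [CohortTable-class], or a [SyntheticSpec-class] (the
#'   spec is re-seeded with `seed` before generation).
#' @param outDir output directory (created if needed); `NULL` for no files.
#' @param nPerm permutations for significance (default 10000).
#' @param nBoot bootstrap replicates for standard errors (default 1000).
#' @param seed integer seed for all stochastic steps.
#' @param ridge optional ridge for [solveCCA()].
#' @param seMethod `"bootstrap"` (default) or `"permutation"`.
#' @param topN variables per set in the text report.
#'
#' @return invisibly, a list with elements `cohort`, `summary`,
#'   `association`, `solution`, `inference`, `paths`.
#' @export
runPipeline <- function(cohort, outDir = NULL, nPerm = 10000, nBoot = 1000,
                        seed = 1, ridge = 0,
                        seMethod = c("bootstrap", "permutation"),
                        topN = 10L) {
  seMethod <- match.arg(seMethod)
  if (is(cohort, "SyntheticSpec"))
    cohort <- generateCohort(reseedSpec(cohort, seed))
  summary <- summarizeCohort(cohort)
  highMissing <- summary$variable[summary$pctMissing > 30]
  for (v in highMissing)
    message("note: variable '", v, "' has > 30% missing values")
  am <- giniCorrelation(giniCovariance(cohort))
  sol <- solveCCA(am, ridge = ridge)
  inf <- inferCCA(cohort, nPerm = nPerm, nBoot = nBoot, seed = seed,
                  seMethod = seMethod)
  paths <- character()
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name, rn = FALSE) {
      p <- file.path(outDir, name)
      utils::write.csv(df, p, row.names = rn)
      p
    }
    paths <- c(paths,
      wr(summary, "descriptives.csv"),
      writeAssociation(am, outDir),
      wr(structuralCoefficients(sol), "loadings.csv"),
      wr(data.frame(variate = seq_len(sol@K), rho = sol@rho,
                    se = inf@standardErrors, pValue = inf@pValues,
                    redundancyY = sol@redundancyY,
                    nPerm = inf@nPerm, seed = inf@seed,
                    statistic = inf@statistic),
         "canonical_correlations.csv"))
    rp <- file.path(outDir, "report.txt")
    writeLines(.fingerReport(sol, inf, summary, topN), rp)
    mf <- file.path(outDir, "manifest.yaml")
    yaml::write_yaml(list(
      package = "giniCCA",
      version = as.character(utils::packageVersion("giniCCA")),
      seed = as.integer(seed), nPerm = as.integer(nPerm),
      nBoot = as.integer(nBoot), ridge = ridge, seMethod = seMethod,
      nSubjects = nSubjects(cohort),
      minPairwiseN = min(pairwiseN(am)),
      highMissingVariables = as.list(highMissing),
      droppedVariables = as.list(sol@dropped),
      repairs = as.list(sol@repairLog)
    ), mf)
    paths <- c(paths, rp, mf)
  }
  invisible(list(cohort = cohort, summary = summary, association = am,
                 solution = sol, inference = inf, paths = paths))
}

#' Persist / restore a pipeline run configuration
#'
#' A run configuration is a plain list (YAML-serializable) with either an
#' `input` entry (`csv` path + `config` set-assignment path) or a `preset`
#' entry (arguments for [encephalitisPreset()]), plus any of `nPerm`,
#' `nBoot`, `seed`, `ridge`, `seMethod`, `outDir`.  A persisted
#' configuration re-runs to identical outputs.
#'
#' @param config a named list.
#' @param path YAML file path.
#' @return `readRunConfig` returns the list; `writeRunConfig` the path,
#'   invisibly.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' @rdname writeRunConfig
#' @param outDir overrides the configuration's `outDir` if non-`NULL`.
#' @export
runPipelineFromConfig <- function(path, outDir = NULL) {
  cfg <- readRunConfig(path)
  cohort <- if (!is.null(cfg$input)) {
    readCohort(cfg$input$csv, cfg$input$config,
               missingToken = cfg$input$missingToken %||% "NA")
  } else {
    do.call(encephalitisPreset, cfg$preset %||% list())
  }
  runPipeline(cohort,
              outDir = outDir %||% cfg$outDir,
              nPerm = cfg$nPerm %||% 10000,
              nBoot = cfg$nBoot %||% 1000,
              seed = cfg$seed %||% 1,
              ridge = cfg$ridge %||% 0,
              seMethod = cfg$seMethod %||% "bootstrap")
}
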