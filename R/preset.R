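## Descriptive counts (present / absent / missing out of n = 208) reported
## for a prospective UK cohort of 208 confirmed encephalitis patients:
## 13 exposure + 2 demographic variables (X) and 18 symptom/clinical +
## 6 diagnostic variables (Y).  Age, hospital stay and illness duration are
## dichotomized at 10 years, 50 days and 100 days respectively.
.encephalitisCounts <- function() {
  x <- rbind(
    c("Sex (male)",            "X", 113,  95,  0),
    c("Age (<=10)",            "X",  55, 146,  7),
    c("Animal Contact",        "X", 101,  95, 12),
    c("Tick Bite",             "X",   7, 188, 13),
    c("Mosquito Bite",         "X",  13, 182, 13),
    c("Insect Bite",           "X",  14, 179, 15),
    c("Immunization",          "X",  14, 182, 12),
    c("Recent Infection",      "X",  78, 113, 17),
    c("Travel Abroad",         "X",  27, 174,  7),
    c("Travel UK",             "X",  31, 164, 13),
    c("Raw Fish",              "X",   7, 184, 17),
    c("Untreated Water",       "X",   6, 185, 17),
    c("Water Exposure",        "X",  38, 157, 13),
    c("Head Trauma",           "X",  23, 173, 12),
    c("Sick Person Contact",   "X",  54, 136, 18),
    c("Abnormal CT",           "Y",  51, 123, 34),
    c("Abnormal MRI",          "Y", 102,  69, 37),
    c("Abnormal EEG",          "Y", 100,  20, 88),
    c("Abnormal Glucose",      "Y",  46,  84, 78),
    c("Abnormal Protein",      "Y", 124,  71, 13),
    c("Abnormal WCC",          "Y", 160,  42,  6),
    c("Lethargy",              "Y", 116,  92,  0),
    c("Irritability",          "Y",  77, 131,  0),
    c("PB Change",             "Y", 133,  75,  0),
    c("Seizure",               "Y", 105, 103,  0),
    c("Stiff Neck",            "Y",  46, 162,  0),
    c("Headache",              "Y", 125,  83,  0),
    c("Fever",                 "Y", 162,  46,  0),
    c("Focal-Neurological",    "Y",  76, 132,  0),
    c("Coma",                  "Y",   8, 200,  0),
    c("Neurological",          "Y",  63, 145,  0),
    c("GI Symptoms",           "Y", 103, 105,  0),
    c("Respiratory",           "Y",  42, 166,  0),
    c("Confusion",             "Y",  74, 134,  0),
    c("Rash",                  "Y",  25, 183,  0),
    c("Photophobia",           "Y",  16, 192,  0),
    c("Urinary",               "Y",  21, 187,  0),
    c("Hospital Stay (<=50d)", "Y", 145,  60,  3),
    c("Duration (<=100d)",     "Y", 167,  31, 10)
  )
  data.frame(
    variable = x[, 1L], set = x[, 2L],
    present = as.integer(x[, 3L]), absent = as.integer(x[, 4L]),
    missing = as.integer(x[, 5L]), stringsAsFactors = FALSE
  )
}

#' Descriptive counts of the encephalitis reference cohort
#'
#' Per-variable counts of present (1), absent (0) and missing subjects
#' reported for a 208-patient UK cohort of confirmed encephalitis cases:
#' 15 exposure/demographic variables and 24 symptom, clinical and diagnostic
#' variables.  These counts parameterize [encephalitisPreset()].
#'
#' @return `data.frame` with columns `variable`, `set` (`"X"`/`"Y"`),
#'   `present`, `absent`, `missing` (counts out of n = 208).
#' @export
encephalitisDescriptives <- function() .encephalitisCounts()

#' Synthetic-cohort preset emulating the encephalitis reference cohort
#'
#' Returns a [SyntheticSpec-class] with the 15 exposure/demographic (X) and
#' 24 symptom/diagnostic (Y) variables of the 208-patient encephalitis
#' reference cohort.  Per-variable prevalences are the reported
#' present-counts over 208 and MCAR missing rates the missing-counts over
#' 208 (see [encephalitisDescriptives()]).  The between-set signal runs
#' from age (the dominant exposure-side variable in the reference analysis)
#' to an equally weighted combination of the symptom-side variables flagged
#' there (abnormal WCC, headache, confusion, abnormal protein, personality/
#' behavioural change, hospital stay, illness duration).
#'
#' @param n subjects (default 208, the reference cohort size).
#' @param rhoLatent latent between-set canonical correlation (default 0.8,
#'   giving a strong — but threshold-attenuated — binary-scale association).
#' @param withinNoise exchangeable within-set latent correlation
#'   (default 0.1, weak within-set dependence).
#' @param missing apply the reference missingness rates (default `TRUE`).
#' @param seed integer RNG seed.
#' @return a [SyntheticSpec-class].
#' @examples
#' spec <- encephalitisPreset(seed = 3)
#' ct <- generateCohort(spec)
#' head(summarizeCohort(ct))
#' @export
encephalitisPreset <- function(n = 208, rhoLatent = 0.8, withinNoise = 0.1,
                               missing = TRUE, seed = 1) {
  tab <- .encephalitisCounts()
  prev <- stats::setNames(tab$present / 208, tab$variable)
  miss <- if (missing) tab$missing / 208 else rep(0, nrow(tab))
  dX <- as.numeric(tab$variable[tab$set == "X"] == "Age (<=10)")
  ySignal <- c("Abnormal WCC", "Headache", "Confusion", "Abnormal Protein",
               "PB Change", "Hospital Stay (<=50d)", "Duration (<=100d)")
  dY <- as.numeric(tab$variable[tab$set == "Y"] %in% ySignal)
  syntheticSpec(prev, sets = tab$set, n = n, missingRates = miss,
                rhoLatent = rhoLatent, directionX = dX, directionY = dY,
                withinNoise = withinNoise, seed = seed)
}
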