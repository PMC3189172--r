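test_that("thresholding recovers the requested prevalences", {
  prev <- c(fever = 0.779, rare = 0.05, mid = 0.4)
  spec <- syntheticSpec(prev, sets = c("Y", "Y", "X"), n = 10000, seed = 6)
  ct <- generateCohort(spec)
  emp <- colMeans(cohortMatrix(ct))
  # 3 * binomial SE per variable
  for (v in names(prev))
    expect_lt(abs(emp[v] - prev[v]), 3 * sqrt(prev[v] * (1 - prev[v]) / 10000))
})

test_that("identical seeds give identical cohorts; different seeds differ", {
  spec <- encephalitisPreset(seed = 9)
  c1 <- generateCohort(spec)
  c2 <- generateCohort(spec)
  expect_identical(cohortMatrix(c1), cohortMatrix(c2))
  c3 <- generateCohort(reseedSpec(spec, 10))
  expect_false(identical(cohortMatrix(c1), cohortMatrix(c3)))
})

test_that("generateCohort leaves the caller's RNG stream untouched", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generateCohort(encephalitisPreset(seed = 4)))
  expect_identical(runif(1), before)
})

test_that("rhoLatent = 0 produces independent sets", {
  prev <- setNames(rep(0.5, 4), paste0("v", 1:4))
  spec <- syntheticSpec(prev, sets = c("X", "X", "Y", "Y"), n = 10000,
                        rhoLatent = 0, seed = 3)
  R <- giniR(giniCorrelation(giniCovariance(generateCohort(spec))))
  # all between-set correlations within Monte-Carlo bounds of zero
  expect_lt(max(abs(R[1:2, 3:4])), 3 / sqrt(10000))
})

test_that("MCAR masking hits the requested rates", {
  prev <- setNames(rep(0.5, 3), c("a", "b", "c"))
  spec <- syntheticSpec(prev, sets = c("X", "Y", "Y"), n = 10000,
                        missingRates = c(0, 0.423, 0.1), seed = 5)
  miss <- colMeans(is.na(cohortMatrix(generateCohort(spec))))
  expect_identical(unname(miss[1]), 0)
  expect_lt(abs(miss[2] - 0.423), 3 * sqrt(0.423 * 0.577 / 10000))
  expect_lt(abs(miss[3] - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))
})

test_that("invalid latent structures are rejected at construction", {
  prev <- setNames(rep(0.5, 4), paste0("v", 1:4))
  expect_error(syntheticSpec(prev, sets = c("X", "X", "Y", "Y"),
                             n = 100, rhoLatent = 1.2), "rhoLatent")
  expect_error(syntheticSpec(prev, sets = c("X", "X", "Y", "Y"),
                             n = 100, missingRates = 1), "missingRates")
  expect_error(syntheticSpec(c(a = 0, b = 0.5), sets = c("X", "Y"), n = 50),
               "prevalences")
  # a spec whose latent structure degenerates fails validity before sampling
  spec <- syntheticSpec(prev, sets = c("X", "X", "Y", "Y"), n = 100,
                        rhoLatent = 0.5, withinNoise = 0.2)
  spec@directionY <- c(0, 0)   # no signal carrier: structure is undefined
  expect_error(generateCohort(spec), "positive semidefinite")
})

test_that("the encephalitis preset transcribes the reference counts", {
  tab <- encephalitisDescriptives()
  expect_identical(nrow(tab), 39L)
  expect_identical(sum(tab$set == "X"), 15L)
  expect_identical(sum(tab$set == "Y"), 24L)
  expect_true(all(tab$present + tab$absent + tab$missing == 208L))

  spec <- encephalitisPreset()
  expect_equal(unname(spec@prevalences["Tick Bite"]), 7 / 208)
  expect_equal(unname(spec@prevalences["Fever"]), 162 / 208)
  miss <- setNames(spec@missingRates, names(spec@prevalences))
  expect_equal(unname(miss["Abnormal EEG"]), 88 / 208)
  expect_identical(unname(variableSets(spec)["Age (<=10)"]), "X")
})

test_that("preset round-trips through generate + summarize at scale", {
  spec <- encephalitisPreset(n = 10000, seed = 11)
  s <- summarizeCohort(generateCohort(spec))
  prev <- spec@prevalences[s$variable]
  # percent present among observed recovers the prevalence parameter
  se3 <- 3 * sqrt(prev * (1 - prev) / (10000 * (1 - spec@missingRates))) * 100
  expect_true(all(abs(s$pctPresentObserved - 100 * prev) <= se3 + 0.05))
})

test_that("estimated rho rises monotonically with the latent coupling", {
  rhoHat <- sapply(c(0, 0.4, 0.8), function(r) {
    spec <- encephalitisPreset(n = 4000, rhoLatent = r, missing = FALSE,
                               seed = 21)
    canonicalCorrelations(solveCCA(generateCohort(spec)))[1]
  })
  expect_true(all(diff(rhoHat) > 0))
  # attenuation: binary-scale correlation sits well below the latent 0.8
  expect_lt(rhoHat[3], 0.8)
})
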