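test_that("cohort generation is bit-reproducible from its seed", {
  cfg <- cohortConfig(nSubjects = 3L, level = 2L, T = 40L, R = 2L, M = 5L,
                      K = 2L, C = 2L, seed = 7L)
  a <- makeCohort(cfg)
  b <- makeCohort(cfg)
  expect_identical(a$subjects[[2]]$runs[[1]]@data,
                   b$subjects[[2]]$runs[[1]]@data)
  expect_identical(a$subjects[[3]]$visits[[2]]@data,
                   b$subjects[[3]]$visits[[2]]@data)
  expect_identical(a$groundTruth$z, b$groundTruth$z)
  # a different seed changes the cohort
  c2 <- makeCohort(cohortConfig(nSubjects = 3L, level = 2L, T = 40L, R = 2L,
                                M = 5L, K = 2L, C = 2L, seed = 8L))
  expect_false(identical(a$groundTruth$z, c2$groundTruth$z))
})

test_that("zero scan noise makes the two visits identical", {
  coh <- makeCohort(cohortConfig(nSubjects = 2L, level = 2L, T = 20L, R = 1L,
                                 M = 4L, K = 2L, C = 2L, sigmaScan = 0,
                                 seed = 5L))
  expect_identical(coh$subjects[[1]]$visits[[1]]@data,
                   coh$subjects[[1]]$visits[[2]]@data)
})

test_that("winner-take-all on the synthetic z-maps recovers the labels", {
  coh <- makeCohort(cohortConfig(nSubjects = 1L, level = 3L, T = 20L, R = 1L,
                                 M = 10L, K = 3L, C = 2L, seed = 11L))
  agree <- mean(coh$parcellation@labels == coh$groundTruth$labels)
  expect_gte(agree, 0.99)
})

test_that("template smoothness: neighbor-difference energy below a raw draw", {
  coh <- makeCohort(cohortConfig(nSubjects = 1L, level = 2L, T = 20L, R = 1L,
                                 M = 5L, K = 2L, C = 3L, seed = 13L))
  m <- coh$mesh
  energy <- function(f) {
    e <- meshEdges(m)
    mean((f[e[, 1]] - f[e[, 2]])^2) / stats::var(f)
  }
  set.seed(14)
  raw <- rnorm(nVertices(m))
  for (c in 1:3)
    expect_lt(energy(coh$groundTruth$templates[, c]), energy(raw))
})

test_that("the oracle predictor realizes the generative ceiling", {
  cfg <- cohortConfig(nSubjects = 6L, level = 2L, T = 20L, R = 1L, M = 5L,
                      K = 2L, C = 3L, sigmaScan = 0.05, seed = 17L)
  coh <- makeCohort(cfg)
  gt <- coh$groundTruth
  # z = 0 subject equals the template exactly
  z0 <- oraclePredictor(gt, z = rep(0, 2))
  expect_identical(z0@data, gt$templates)
  # oracle at least matches the template reference for every subject
  targets <- lapply(coh$subjects, function(s) s$visits[[1]])
  for (i in seq_along(targets)) {
    oAuc <- mean(vapply(1:3, function(c)
      diceAUC(oraclePredictor(gt, i)@data[, c], targets[[i]]@data[, c])@auc, 1))
    tAuc <- mean(vapply(1:3, function(c)
      diceAUC(gt$templates[, c], targets[[i]]@data[, c])@auc, 1))
    expect_gte(oAuc, tAuc)
  }
  # oracle identification is perfect at low scan noise
  preds <- lapply(seq_along(targets), function(i) oraclePredictor(gt, i)@data[, 1])
  tg <- lapply(targets, function(t) t@data[, 1])
  expect_equal(identificationMatrix(preds, tg)@accuracy, 1)
})

test_that("repeat reliability decreases monotonically with scan noise", {
  rel <- function(sigma) {
    coh <- makeCohort(cohortConfig(nSubjects = 5L, level = 2L, T = 20L,
                                   R = 1L, M = 5L, K = 2L, C = 2L,
                                   sigmaScan = sigma, seed = 21L))
    mean(vapply(coh$subjects, function(s)
      diceAUC(s$visits[[2]]@data[, 1], s$visits[[1]]@data[, 1])@auc, 1))
  }
  r <- vapply(c(0.05, 0.3, 1.0), rel, 1)
  expect_true(all(diff(r) < 0))
})

test_that("transfer cohorts share tasks but shift domain", {
  base <- makeCohort(cohortConfig(nSubjects = 3L, level = 2L, T = 40L,
                                  R = 1L, M = 5L, K = 2L, C = 2L, seed = 23L))
  shifted <- makeCohort(cohortConfig(nSubjects = 3L, level = 2L, T = 40L,
                                     R = 1L, M = 5L, K = 2L, C = 2L,
                                     seed = 24L),
                        groundTruth = base$groundTruth,
                        templateShift = 0.5, loadingShift = 0.3)
  gt0 <- base$groundTruth; gt1 <- shifted$groundTruth
  expect_identical(gt1$D, gt0$D)                 # coupling fields shared
  expect_identical(gt1$seeds, gt0$seeds)         # parcellation shared
  expect_false(identical(gt1$templates, gt0$templates))
  expect_false(identical(gt1$base, gt0$base))
  # template shift magnitude is as configured (0.5 sd, unit-sd fields)
  shift <- gt1$templates - gt0$templates
  expect_equal(stats::sd(as.vector(shift)), 0.5, tolerance = 0.2)
  expect_error(makeCohort(cohortConfig(nSubjects = 2L, level = 2L, T = 40L,
                                       R = 1L, M = 5L, K = 2L, C = 4L,
                                       seed = 25L),
                          groundTruth = base$groundTruth), "dimensions")
})

test_that("configuration invariants are enforced", {
  expect_error(cohortConfig(K = 9L, M = 4L), "K")
  expect_error(cohortConfig(visits = 0L), "visit")
  expect_error(cohortConfig(link = "cubic"), "link")
  expect_error(cohortConfig(nSubjects = 0L), "positive")
})
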