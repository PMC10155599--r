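gradCheck <- function(spec, V, eps = 1e-6, nPerParam = 4L, seed = 99L) {
  model <- buildModel(spec)
  set.seed(seed)
  x <- matrix(rnorm(V * spec@inChannels), V)
  tgt <- matrix(rnorm(V * spec@outChannels), V)
  lossOf <- function(m) mean((surftask:::modelForward(m, x) - tgt)^2)
  fw <- surftask:::modelForward(model, x, cache = TRUE)
  dOut <- 2 * (fw$out - tgt) / length(tgt)
  gr <- surftask:::modelBackward(model, fw, dOut)
  worst <- 0
  for (nm in names(model@params)) {
    p <- model@params[[nm]]
    for (i in sample(length(p), min(nPerParam, length(p)))) {
      m2 <- model; m2@params[[nm]][i] <- p[i] + eps
      m3 <- model; m3@params[[nm]][i] <- p[i] - eps
      num <- (lossOf(m2) - lossOf(m3)) / (2 * eps)
      rel <- abs(num - gr[[nm]][i]) / max(1e-8, abs(num) + abs(gr[[nm]][i]))
      worst <- max(worst, rel)
    }
  }
  worst
}

test_that("forward pass obeys the shape contract and is deterministic", {
  spec <- modelSpec(3, 2, inChannels = 10, outChannels = 6,
                    widths = c(8L, 12L, 16L), seed = 3)
  m <- buildModel(spec)
  x <- matrix(rnorm(642 * 10), 642)
  out <- surftask:::modelForward(m, x)
  expect_identical(dim(out), c(642L, 6L))
  expect_identical(out, surftask:::modelForward(m, x))
  # same seed twice -> identical initial parameters
  expect_identical(m@params, buildModel(spec)@params)
})

test_that("skip connections change decoder input widths by the encoder widths", {
  on <- buildModel(modelSpec(2, 2, 4, 2, widths = c(5L, 7L, 9L), seed = 1))
  off <- buildModel(modelSpec(2, 2, 4, 2, widths = c(5L, 7L, 9L),
                              skip = FALSE, seed = 1))
  # dec s consumes widths[s+1] (+ widths[s] when skipping)
  expect_identical(dim(on@params[["dec1.W"]])[2], 7L + 5L)
  expect_identical(dim(off@params[["dec1.W"]])[2], 7L)
  expect_identical(dim(on@params[["dec2.W"]])[2], 9L + 7L)
  expect_identical(dim(off@params[["dec2.W"]])[2], 9L)
})

test_that("analytic gradients agree with central differences", {
  # tiny V=12 model
  worst0 <- gradCheck(modelSpec(0, 0, 2, 3, widths = 6L, seed = 4), 12)
  expect_lt(worst0, 1e-4)
  # full topology: skips, pooling, instance norm
  worst2 <- gradCheck(modelSpec(2, 2, 3, 2, widths = c(5L, 7L, 9L), seed = 5),
                      162)
  expect_lt(worst2, 1e-4)
  # no-norm no-skip variant
  worst3 <- gradCheck(modelSpec(1, 1, 3, 2, widths = c(5L, 7L), skip = FALSE,
                                normalization = "none", seed = 6), 42)
  expect_lt(worst3, 1e-4)
})

test_that("replaceHead re-initializes the head and preserves the backbone", {
  m <- buildModel(modelSpec(1, 1, 3, 4, widths = c(6L, 8L), seed = 11))
  m2 <- replaceHead(m, 4, seed = 12)
  backbone <- function(mm) mm@params[!startsWith(names(mm@params), "head.")]
  expect_identical(backbone(m2), backbone(m))
  expect_false(identical(m2@params[["head.W"]], m@params[["head.W"]]))
  m3 <- replaceHead(m, 2, seed = 13)
  out <- surftask:::modelForward(m3, matrix(rnorm(42 * 3), 42))
  expect_identical(ncol(out), 2L)
  expect_error(replaceHead(m, 0, 1), ">= 1")
})

test_that("freezing a partition keeps it bit-identical under training", {
  coh <- tinyCohort(seed = 21L, n = 4L)
  conns <- cohortConnectomes(coh)
  td <- cohortTrainingData(coh, conns)
  m <- buildModel(modelSpec(2, 1, 6, 3, widths = c(6L, 8L), seed = 2))
  headOf <- function(mm) mm@params[startsWith(names(mm@params), "head.")]
  backboneOf <- function(mm) mm@params[!startsWith(names(mm@params), "head.")]

  frozenHead <- trainModel(setTrainable(m, "backbone"), td,
                           list(phaseSpec("mse", epochs = 2)), seed = 5)
  expect_identical(headOf(frozenHead), headOf(m))
  expect_false(identical(backboneOf(frozenHead), backboneOf(m)))

  frozenBack <- trainModel(setTrainable(m, "head"), td,
                           list(phaseSpec("mse", epochs = 2)), seed = 5)
  expect_identical(backboneOf(frozenBack), backboneOf(m))
  expect_false(identical(headOf(frozenBack), headOf(m)))

  expect_error(setTrainable(m, character(0)), "trainable")
})

test_that("checkpoint save/load round-trips parameters and spec", {
  m <- buildModel(modelSpec(1, 0, 2, 2, widths = 5L, seed = 9))
  p <- tempfile(fileext = ".rds")
  saveModel(m, p)
  m2 <- loadModel(p)
  expect_identical(m2@params, m@params)
  expect_identical(m2@spec@widths, m@spec@widths)
  expect_true(file.exists(paste0(p, ".json")))
})

test_that("skip connections do not hurt reconstruction at matched budget", {
  coh <- tinyCohort(seed = 42L)
  conns <- cohortConnectomes(coh)
  td <- cohortTrainingData(coh, conns, indices = 1:8)
  vd <- cohortTrainingData(coh, conns, indices = 9:10)
  valLoss <- function(skip, seed) {
    sp <- modelSpec(2, 1, inChannels = 6, outChannels = 3,
                    widths = c(12L, 16L), skip = skip, seed = seed)
    m <- trainModel(buildModel(sp), td,
                    list(phaseSpec("mse", epochs = 8, lr = 3e-3)),
                    valSubjects = vd, seed = seed)
    min(m@history$val)
  }
  withSkip <- vapply(1:3, function(s) valLoss(TRUE, s), 1)
  without <- vapply(1:3, function(s) valLoss(FALSE, s), 1)
  expect_lte(median(withSkip), median(without))
})
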