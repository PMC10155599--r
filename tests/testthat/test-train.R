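test_that("the R-C loss reproduces worked arithmetic and pair counts", {
  # scalar maps: d(a, b) = (a - b)^2
  # perfect predictions, alpha 0, gamma 1, cross distance large -> loss 0
  preds <- lapply(c(0, 5), scalarMap)
  targets <- lapply(c(0, 5), scalarMap)
  rep0 <- rcLoss(preds, targets, lossConfig(alpha = 0, gamma = 1))
  expect_equal(rep0@lR, 0)
  expect_equal(rep0@lC, 25)                      # d(0,5) = d(5,0) = 25
  expect_equal(rep0@lRC, 0)                      # [0-0]+ + [0-25+1]+ = 0

  # L_R = 2, alpha = 1, L_C = 3, gamma = 2 -> L_RC = 1 + 1 = 2, by direct
  # arithmetic of the hinge identity
  cfg <- lossConfig(alpha = 1, gamma = 2)
  expect_equal(max(2 - cfg@alpha, 0) + max(2 - 3 + cfg@gamma, 0), 2)
  # and the implementation satisfies the same identity on real batches
  set.seed(8)
  P <- lapply(1:4, function(i) matrix(rnorm(30), 10, 3))
  Tm <- lapply(1:4, function(i) matrix(rnorm(30), 10, 3))
  r <- rcLoss(P, Tm, lossConfig(alpha = 0.7, gamma = 0.9))
  expect_equal(r@lRC, max(r@lR - 0.7, 0) + max(r@lR - r@lC + 0.9, 0))
  expect_identical(r@nPairs, 6L)                 # (4^2 - 4) / 2
  expect_identical(r@n, 4L)
})

test_that("single-subject batches fall back to the reconstructive hinge", {
  expect_message(
    r <- rcLoss(list(scalarMap(2)), list(scalarMap(0)),
                lossConfig(alpha = 1)),
    "single-subject")
  expect_equal(r@lRC, 3)                         # [4 - 1]+
  expect_error(rcLoss(list(scalarMap(1)), list(scalarMap(1)),
                      lossConfig(channelMask = FALSE)), "channel")
})

test_that("loss limits: infinite alpha and dominant gamma", {
  set.seed(9)
  P <- lapply(1:3, function(i) matrix(rnorm(20), 10, 2))
  Tm <- lapply(1:3, function(i) matrix(rnorm(20), 10, 2))
  # alpha -> Inf, gamma = 0: first hinge vanishes, pure contrast-gap hinge
  rInf <- rcLoss(P, Tm, lossConfig(alpha = Inf, gamma = 0))
  expect_equal(rInf@lRC, max(rInf@lR - rInf@lC, 0))
  # gamma so large that L_C never catches up: hinged-MSE behavior
  rBig <- rcLoss(P, Tm, lossConfig(alpha = 0.5, gamma = 1e6))
  expect_equal(rBig@lRC,
               max(rBig@lR - 0.5, 0) + (rBig@lR - rBig@lC + 1e6))
})

test_that("margins initialize from the converged model and follow the schedule", {
  coh <- tinyCohort(seed = 51L, n = 4L)
  conns <- cohortConnectomes(coh)
  td <- cohortTrainingData(coh, conns)
  m <- buildModel(modelSpec(2, 1, 6, 3, widths = c(6L, 8L), seed = 3))
  connsL <- lapply(td, `[[`, "connectomes")
  tgts <- lapply(td, `[[`, "target")
  mi <- initMargins(m, connsL, tgts)
  mi2 <- initMargins(m, connsL, tgts)
  expect_identical(mi, mi2)                      # deterministic
  expect_equal(mi$alpha0, mi$lR)
  expect_equal(mi$gamma0, max(mi$lC - mi$lR, 0))
  full <- initMargins(m, connsL, tgts, rule = "full")
  expect_equal(full$gamma0, full$lC)
  # a model with zero training error has alpha0 = 0
  perfect <- lapply(seq_along(tgts), function(i)
    list(connectomes = connsL[[i]], target = tgts[[i]]))
  predsAsTargets <- lapply(connsL, function(cs) {
    p <- surftask:::modelForward(m, surftask:::prepInput(m, cs[[1]]))
    new("ContrastMaps", data = p, vertexMask = rep(TRUE, nrow(p)),
        subject = "x", contrastNames = sprintf("c%d", seq_len(ncol(p))))
  })
  mi0 <- initMargins(m, connsL, predsAsTargets)
  expect_equal(mi0$alpha0, 0, tolerance = 1e-12)

  expect_identical(marginSchedule(1, 2, 0), list(alpha = 1, gamma = 2))
  expect_identical(marginSchedule(1, 2, 19), list(alpha = 1, gamma = 2))
  expect_identical(marginSchedule(1, 2, 20), list(alpha = 0.5, gamma = 4))
  expect_identical(marginSchedule(1, 2, 45), list(alpha = 0.25, gamma = 8))
  expect_error(marginSchedule(1, 2, -1), "epoch")
})

test_that("training reduces the loss and is bit-reproducible", {
  coh <- tinyCohort(seed = 61L, n = 4L)
  conns <- cohortConnectomes(coh)
  td <- cohortTrainingData(coh, conns, indices = 1:2)
  sp <- modelSpec(2, 1, 6, 3, widths = c(6L, 8L), seed = 5)
  m1 <- trainModel(buildModel(sp), td, list(phaseSpec("mse", epochs = 5)),
                   seed = 7)
  dl <- diff(m1@history$loss)
  expect_gte(sum(dl <= 0), 3)                    # non-increasing in >= 4 of 5
  m2 <- trainModel(buildModel(sp), td, list(phaseSpec("mse", epochs = 5)),
                   seed = 7)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@history, m2@history)
  expect_error(trainModel(buildModel(sp), list(), list(phaseSpec("mse", 1))),
               "empty")
  expect_error(phaseSpec("rc", 5, batchSize = 1L), "batch")
})

test_that("the R-C phase logs margins that change exactly on schedule", {
  coh <- tinyCohort(seed = 71L, n = 4L)
  conns <- cohortConnectomes(coh)
  td <- cohortTrainingData(coh, conns)
  sp <- modelSpec(2, 1, 6, 3, widths = c(6L, 8L), seed = 5)
  m <- trainModel(buildModel(sp), td,
                  list(phaseSpec("mse", epochs = 2),
                       phaseSpec("rc", epochs = 5, marginPeriod = 2L)),
                  seed = 7)
  h <- m@history[m@history$objective == "rc", ]
  expect_equal(h$alpha[2] / h$alpha[1], 1)       # epochs 0,1 share margins
  expect_equal(h$alpha[3] / h$alpha[1], 0.5)     # halved at epoch 2
  expect_equal(h$gamma[3] / h$gamma[1], 2)
  expect_equal(h$alpha[5] / h$alpha[1], 0.25)
})

test_that("channel-masked training sends no gradient from held-out targets", {
  m <- buildModel(modelSpec(1, 0, 3, 3, widths = 6L, seed = 8))
  set.seed(10)
  x <- matrix(rnorm(42 * 3), 42)
  tgtA <- matrix(rnorm(42 * 3), 42)
  tgtB <- tgtA
  tgtB[, 1] <- rnorm(42)                         # perturb only channel 1
  vmask <- rep(TRUE, 42)
  cmask <- c(FALSE, TRUE, TRUE)
  gradsOf <- function(tgt) {
    fw <- surftask:::modelForward(m, x, cache = TRUE)
    lo <- surftask:::mseLossCore(list(fw$out), list(tgt), vmask, cmask)
    surftask:::modelBackward(m, fw, lo$grads[[1]])
  }
  expect_identical(gradsOf(tgtA), gradsOf(tgtB))
})

test_that("finetuning modes honor their contracts", {
  coh <- tinyCohort(seed = 81L, n = 6L)
  conns <- cohortConnectomes(coh)
  td <- cohortTrainingData(coh, conns, indices = 1:4)
  base <- trainModel(buildModel(modelSpec(2, 1, 6, 3, widths = c(6L, 8L),
                                          seed = 2)),
                     td, list(phaseSpec("mse", epochs = 2)), seed = 3)
  # full_with_new_head to C = 2 predicts 2 channels
  ft <- finetuneModel(base, td2 <- lapply(td, function(s) {
    s$target@data <- s$target@data[, 1:2]
    s$target@contrastNames <- s$target@contrastNames[1:2]
    s
  }), "full_with_new_head", epochs = 1, cNew = 2, seed = 4)
  expect_identical(ft@spec@outChannels, 2L)
  # backbone_only: head bit-identical, masked channel gets no gradient
  expect_warning(finetuneModel(base, td, "backbone_only", epochs = 1,
                               seed = 4), "held-out")
  bo <- finetuneModel(base, td, "backbone_only", epochs = 2, seed = 4,
                      channelMask = c(FALSE, TRUE, TRUE))
  headOf <- function(mm) mm@params[startsWith(names(mm@params), "head.")]
  expect_identical(headOf(bo), headOf(base))
  # denovo ignores pretrained weights: equals fresh build + train
  dn <- finetuneModel(base, td, "denovo", epochs = 2, seed = 6)
  sp <- base@spec; sp@seed <- 6L
  ref <- trainModel(buildModel(sp), td,
                    list(phaseSpec("mse", epochs = 2, batchSize = 2L,
                                   lr = 1e-3)), seed = 6)
  expect_identical(dn@params, ref@params)
})

test_that("test-time ensembling averages forward passes", {
  coh <- tinyCohort(seed = 91L, n = 2L)
  conns <- cohortConnectomes(coh)
  m <- buildModel(modelSpec(2, 0, 6, 3, widths = 6L, seed = 1))
  single <- ensemblePredict(m, conns[[1]][[1]])
  fw <- surftask:::modelForward(m, surftask:::prepInput(m, conns[[1]][[1]]))
  expect_identical(single@data, fw)
  dup <- ensemblePredict(m, rep(conns[[1]][1], 3))
  expect_equal(dup@data, single@data, tolerance = 1e-15)
  two <- ensemblePredict(m, conns[[1]][1:2])
  fw2 <- surftask:::modelForward(m, surftask:::prepInput(m, conns[[1]][[2]]))
  expect_equal(two@data, (fw + fw2) / 2, tolerance = 1e-15)
  expect_error(ensemblePredict(m, list()), "empty")
})
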