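test_that("top-fraction sets match an exhaustive sort oracle", {
  expect_identical(topFracSet(10:1, 0.2), c(1L, 2L))
  expect_identical(topFracSet(10:1, 1.0), 1:10)
  # masked vertices never enter
  expect_identical(topFracSet(10:1, 0.2, mask = c(FALSE, rep(TRUE, 9))),
                   c(2L, 3L))
  # deactivated / absolute modes
  expect_identical(topFracSet(c(-5, 1, 2, -7, 0), 0.4, mode = "deactivated"),
                   c(1L, 4L))
  expect_identical(topFracSet(c(-5, 1, 2, -7, 0), 0.4, mode = "absolute"),
                   c(1L, 4L))
  set.seed(12)
  for (trial in 1:300) {
    v <- rnorm(30)
    x <- runif(1, 0.04, 1)
    k <- max(1L, round(x * 30))
    oracle <- sort(order(-v, seq_along(v))[seq_len(k)])
    expect_identical(topFracSet(v, x), oracle)
  }
  expect_error(topFracSet(1:5, 0.5, mask = rep(FALSE, 5)), "empty")
  expect_error(topFracSet(1:5, 0), "fraction")
})

test_that("dice overlap matches set arithmetic and is symmetric", {
  v <- seq(10, 1)
  expect_equal(diceAt(v, v, 0.2), 1)
  expect_equal(diceAt(v, -v + 0.01 * seq(10), 0.2), 0)  # disjoint top sets
  set.seed(13)
  for (trial in 1:300) {
    a <- rnorm(40); b <- rnorm(40); x <- runif(1, 0.05, 0.9)
    A <- topFracSet(a, x); B <- topFracSet(b, x)
    expect_identical(diceAt(a, b, x),
                     2 * length(intersect(A, B)) / (length(A) + length(B)))
    expect_identical(diceAt(a, b, x), diceAt(b, a, x))  # equal-k symmetry
  }
  expect_error(diceAt(rnorm(5), rnorm(6), 0.2), "meshes")
})

test_that("Dice AUC integrates the curve and is rank-invariant", {
  set.seed(14)
  a <- rnorm(100)
  dc <- diceAUC(a, a)
  expect_equal(dc@auc, 0.45)
  expect_identical(dc@thresholds, seq(0.05, 0.50, by = 0.05))
  b <- rnorm(100)
  d2 <- diceAUC(a, b)
  # composite trapezoid of its own curve
  expect_equal(d2@auc, pracma::trapz(d2@thresholds, d2@dice))
  # closed-form check: a linear curve from 0 at 0.05 to 1 at 0.50
  expect_equal(pracma::trapz(seq(0.05, 0.50, 0.05),
                             seq(0, 1, length.out = 10)), 0.225)
  # invariance under strictly increasing monotone transforms
  d3 <- diceAUC(exp(a), b^3 + 5 * b)
  expect_equal(d3@dice, d2@dice)
  expect_true(d2@auc >= 0 && d2@auc <= 0.45 + 1e-12)
})

test_that("whole-brain R^2 behaves at its reference points", {
  set.seed(15)
  y <- matrix(rnorm(50 * 2), 50)
  expect_equal(wholeBrainR2(y, y)$mean, 1)
  const <- matrix(rep(colMeans(y), each = 50), 50)
  expect_equal(wholeBrainR2(const, y)$mean, 0, tolerance = 1e-12)
  # a prediction worse than the mean: hand case
  yh <- c(0, 0, 3); yt <- c(1, 2, 3)   # SSres = 1+4+0 = 5, SStot = 2
  expect_equal(wholeBrainR2(yh, yt)$mean, 1 - 5 / 2)
  expect_true(is.na(wholeBrainR2(rnorm(5), rep(1, 5))$mean))
})

test_that("identification accuracy counts strict diagonal maxima", {
  maps <- lapply(1:4, function(i) { set.seed(100 + i); rnorm(80) })
  im <- identificationMatrix(maps, maps)
  expect_equal(im@accuracy, 1)
  expect_identical(dim(im@aucMatrix), c(4L, 4L))
  # noise-only predictions: compare against a loop oracle on the matrix
  set.seed(16)
  noise <- lapply(1:4, function(i) rnorm(80))
  im2 <- identificationMatrix(noise, maps)
  A <- im2@aucMatrix
  oracle <- mean(vapply(1:4, function(j) A[j, j] > max(A[-j, j]), TRUE))
  expect_equal(im2@accuracy, oracle)
  # invariance under simultaneous relabeling
  perm <- c(3, 1, 4, 2)
  im3 <- identificationMatrix(noise[perm], maps[perm])
  expect_equal(im3@accuracy, im2@accuracy)
  # a tie on the diagonal counts as failure
  expect_equal(surftask:::identAccuracy(matrix(1, 3, 3)), 0)
  expect_error(identificationMatrix(maps[1], maps[1]), "2 subjects")
})

test_that("reliability screening flags contrasts by repeat-vs-group AUC", {
  coh <- tinyCohort(seed = 55L, n = 6L)
  targets <- lapply(coh$subjects, function(s) s$visits[[1]])
  ga <- groupAverage(targets)
  # repeats identical to targets: necessarily reliable
  rs1 <- reliabilityScreen(targets, targets, ga)
  expect_true(all(rs1$reliable))
  # pure-noise repeats against a group average equal to the target mean
  set.seed(17)
  noiseReps <- lapply(targets, function(t) {
    t@data <- matrix(rnorm(length(t@data)), nrow(t@data))
    t
  })
  rs2 <- reliabilityScreen(targets, noiseReps, ga)
  expect_false(any(rs2$reliable))
  expect_error(reliabilityScreen(targets, targets[1:2], ga), "repeat")
})

test_that("higher scan noise lowers repeat reliability", {
  reliability <- function(sigma) {
    coh <- makeCohort(cohortConfig(nSubjects = 6L, level = 2L, T = 20L,
                                   R = 1L, M = 6L, K = 2L, C = 3L,
                                   sigmaScan = sigma, seed = 99L))
    targets <- lapply(coh$subjects, function(s) s$visits[[1]])
    reps <- lapply(coh$subjects, function(s) s$visits[[2]])
    mean(vapply(seq_along(targets), function(i)
      mean(vapply(1:3, function(c)
        diceAUC(reps[[i]]@data[, c], targets[[i]]@data[, c])@auc, 1)), 1))
  }
  r <- vapply(c(0.05, 0.4, 1.5), reliability, 1)
  expect_true(all(diff(r) < 0))
})

test_that("the evaluation report is tidy and complete", {
  coh <- tinyCohort(seed = 65L, n = 3L)
  targets <- lapply(coh$subjects, function(s) s$visits[[1]])
  ga <- groupAverage(targets)
  f <- tempfile(fileext = ".csv")
  rep <- evaluationReport(list(group_avg = ga), targets, file = f)
  expect_identical(nrow(rep), 3L * 3L)           # subjects x contrasts
  expect_true(all(sprintf("dice_%02d", seq(5, 50, 5)) %in% names(rep)))
  expect_true(all(c("subject", "contrast", "comparator", "auc", "r2")
                  %in% names(rep)))
  expect_true(file.exists(f))
})
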