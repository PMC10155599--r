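test_that("winner-take-all picks the highest z with documented tie-breaks", {
  p <- winnerTakeAll(rbind(c(0.1, 3.0, 2.0), c(2, 2, 1), c(-1, -2, -3)))
  expect_identical(p@labels[1], 2L)
  expect_identical(p@labels[2], 1L)   # tie -> lowest component
  expect_identical(p@labels[3], 1L)   # all-negative still assigned
  set.seed(1)
  z <- matrix(rnorm(50 * 5), 50)
  wta <- winnerTakeAll(z)@labels
  brute <- vapply(1:50, function(v) which.max(z[v, ]), 1L)
  expect_identical(wta, brute)
  # z-floor leaves sub-threshold vertices unassigned
  z2 <- rbind(c(5, 0, 0), c(0.1, 0, 0), c(0, 4, 0), c(0, 0, 3))
  expect_true(is.na(winnerTakeAll(z2, zFloor = 1)@labels[2]))
  expect_error(winnerTakeAll(rbind(c(1, NaN))), "finite")
})

test_that("ROI mean timeseries averages exactly the member vertices", {
  ts <- randomTimeseries(V = 6L, Tn = 10L, seed = 2)
  z <- matrix(-1, 6, 3)
  z[cbind(1:6, c(1, 2, 2, 3, 3, 3))] <- 1
  parc <- winnerTakeAll(z)
  rm <- roiMeanTimeseries(ts, parc)
  expect_identical(rm[1, ], ts@data[1, ])                       # singleton ROI
  expect_equal(rm[3, ], colMeans(ts@data[4:6, ]), tolerance = 1e-15)
  # loop oracle over a random assignment
  set.seed(3)
  z2 <- matrix(rnorm(6 * 2), 6)
  parc2 <- winnerTakeAll(z2)
  rm2 <- roiMeanTimeseries(ts, parc2)
  for (j in 1:2)
    expect_equal(rm2[j, ], colMeans(ts@data[parc2@labels == j, , drop = FALSE]))
  # antipodal series cancel
  ts2 <- ts
  ts2@data[5, ] <- -ts2@data[4, ]
  z3 <- matrix(c(rep(1, 6), rep(0, 6)), 6)
  z3[4:5, ] <- rep(c(0, 1), each = 2)
  expect_equal(roiMeanTimeseries(ts2, winnerTakeAll(z3))[2, ],
               rep(0, 10), tolerance = 1e-15)
})

test_that("vertex-to-ROI correlation matches textbook Pearson", {
  ts <- randomTimeseries(V = 20L, Tn = 50L, seed = 4)
  set.seed(5)
  roi <- matrix(rnorm(4 * 50), 4)
  conn <- vertexToRoiFC(ts, roi)
  oracle <- matrix(0, 20, 4)
  for (i in 1:20) for (j in 1:4) oracle[i, j] <- cor(ts@data[i, ], roi[j, ])
  expect_lt(max(abs(conn@data - oracle)), 1e-12)
  # exact matches at the extremes
  ts2 <- ts
  ts2@data[1, ] <- roi[1, ]
  ts2@data[2, ] <- -roi[2, ]
  conn2 <- vertexToRoiFC(ts2, roi)
  expect_equal(conn2@data[1, 1], 1)
  expect_equal(conn2@data[2, 2], -1)
  # degenerate series yield 0 with a warning, not NaN
  ts3 <- ts
  ts3@data[3, ] <- 7
  expect_warning(conn3 <- vertexToRoiFC(ts3, roi), "degenerate")
  expect_identical(conn3@data[3, ], rep(0, 4))
  expect_error(vertexToRoiFC(ts, roi[, 1:10]), "mismatch")
})

test_that("connectomes are invariant to positive affine vertex transforms", {
  ts <- randomTimeseries(V = 8L, Tn = 40L, seed = 6)
  set.seed(7)
  roi <- matrix(rnorm(3 * 40), 3)
  base <- vertexToRoiFC(ts, roi)@data
  ts@data <- ts@data * 2.5 + 11
  expect_equal(vertexToRoiFC(ts, roi)@data, base, tolerance = 1e-12)
})

test_that("hemisphere concatenation doubles channels and round-trips", {
  mk <- function(M, seed) {
    set.seed(seed)
    new("Connectome", data = matrix(runif(30 * M, -1, 1), 30),
        vertexMask = rep(TRUE, 30), subject = "s",
        channelNames = sprintf("roi%02d", seq_len(M)))
  }
  both <- concatHemispheres(mk(42, 1), mk(42, 2))
  expect_identical(ncol(both@data), 84L)
  tiny <- concatHemispheres(mk(1, 3), mk(1, 4))
  expect_identical(ncol(tiny@data), 2L)
  l <- mk(5, 5); r <- mk(5, 6)
  cat5 <- concatHemispheres(l, r)
  expect_identical(cat5@data[, 1:5], l@data)
  expect_identical(cat5@data[, 6:10], r@data)
  expect_error(concatHemispheres(mk(3, 7), mk(4, 8)), "mismatch")
})

test_that("segment splitting yields the documented augmentation counts", {
  mkRun <- function(Tn) new("SurfaceTimeseries",
                            data = matrix(rnorm(5 * Tn), 5),
                            vertexMask = rep(TRUE, 5),
                            hemisphere = "single", tr = 0.72)
  runs <- replicate(4, mkRun(1200), simplify = FALSE)
  halves <- splitSegments(runs, "halves")
  expect_length(halves, 8L)
  expect_true(all(vapply(halves, function(s) ncol(s@data), 1L) == 600L))
  # contiguity and non-overlap
  expect_identical(halves[[1]]@data, runs[[1]]@data[, 1:600])
  expect_identical(halves[[2]]@data, runs[[1]]@data[, 601:1200])

  segs <- splitSegments(list(mkRun(480)), "fixed", length = 120L)
  expect_length(segs, 4L)
  run800 <- mkRun(800)
  r1 <- splitSegments(list(run800), "random", length = 600L, count = 2L,
                      seed = 9L)
  r2 <- splitSegments(list(run800), "random", length = 600L, count = 2L,
                      seed = 9L)
  expect_identical(lapply(r1, values), lapply(r2, values))
  expect_error(splitSegments(list(mkRun(100)), "fixed", length = 200L),
               "exceeds")
})

test_that("channel normalization centers training data and reuses stats", {
  coh <- tinyCohort(seed = 31L, n = 4L)
  conns <- unlist(cohortConnectomes(coh), recursive = FALSE)
  nm <- normalizeChannels(conns[1:12])
  all <- do.call(rbind, lapply(nm$connectomes, `[[`, "data"))
  expect_lt(max(abs(colMeans(all))), 1e-10)
  expect_equal(apply(all, 2, sd), rep(1, ncol(all)), tolerance = 1e-8)
  # eval subject scaled with training stats, not its own
  ev <- normalizeChannels(conns[[13]], stats = nm$stats)
  expect_equal(ev$connectomes$data,
               sweep(sweep(conns[[13]]@data, 2, nm$stats$mean), 2,
                     nm$stats$sd, "/"))
  # apply-then-invert is the identity
  back <- surftask:::invertChannelStats(ev$connectomes$data, nm$stats)
  expect_equal(back, conns[[13]]@data, tolerance = 1e-12)
})

test_that("connectomes fingerprint subjects across runs", {
  coh <- tinyCohort(seed = 77L)
  conns <- cohortConnectomes(coh)
  n <- length(conns)
  # segments 1-2 come from run 1, segments 3-4 from run 2
  within <- vapply(seq_len(n), function(i)
    cor(as.vector(conns[[i]][[1]]@data), as.vector(conns[[i]][[3]]@data)), 1)
  across <- vapply(seq_len(n - 1), function(i)
    cor(as.vector(conns[[i]][[1]]@data), as.vector(conns[[i + 1]][[1]]@data)), 1)
  expect_gt(median(within), median(across))
})
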