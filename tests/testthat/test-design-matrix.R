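test_that("tent bases are 1 at their anchor and a partition of unity between anchors", {
  anchors <- c(-0.1, 0, 0.1)
  W <- tentBasisEval(anchors, anchors)
  expect_equal(W, diag(3))
  Wmid <- tentBasisEval(anchors, c(-0.05, 0.05))
  expect_equal(Wmid[1, ], c(0.5, 0.5, 0))
  expect_equal(Wmid[2, ], c(0, 0.5, 0.5))
  tIn <- seq(-0.1, 0.1, by = 0.004)
  expect_equal(rowSums(tentBasisEval(anchors, tIn)), rep(1, length(tIn)))
  # taper: zero beyond one gap outside; clamp: constant extension
  expect_equal(tentBasisEval(anchors, c(-0.25, 0.25))[, c(1, 3)],
               matrix(0, 2, 2))
  expect_equal(tentBasisEval(anchors, c(-5, 5), boundary = "clamp"),
               rbind(c(1, 0, 0), c(0, 0, 1)))
  expect_error(tentBasisEval(c(0, 0), 0), "strictly increasing")
})

test_that("event kernels have the stated width and sum for overlapping events", {
  bw <- 1 / 60
  bins <- data.frame(time = (0:599) * bw, trial = rep(1:2, each = 300))
  X <- eventKernelColumns(c(1.0), 1, c(0, 0.25), bw, bins)
  expect_equal(ncol(X), 15L)                 # 250 ms at 60 Hz
  expect_equal(attr(X, "shifts"), 0:14)

  none <- eventKernelColumns(numeric(0), numeric(0), c(0, 0.25), bw, bins)
  expect_equal(dim(none), c(600L, 15L))
  expect_true(all(none == 0))

  # two events closer than the window: contributions sum (brute force)
  ons <- c(1.0, 1.1)
  X2 <- eventKernelColumns(ons, c(1, 1), c(0, 0.25), bw, bins)
  oracle <- matrix(0, 600, 15)
  for (e in seq_along(ons)) {
    b <- floor(ons[e] / bw + 1e-9) + 1
    for (d in 0:14) if (b + d <= 300) oracle[b + d, d + 1] <-
        oracle[b + d, d + 1] + 1
  }
  expect_equal(unclass(X2)[, ], oracle, ignore_attr = TRUE)
  expect_error(eventKernelColumns(100, 1, c(0, 0.25), bw, bins), "bounds")
})

test_that("kernel locality holds on random event sets and respects trials", {
  bw <- 1 / 60
  bins <- data.frame(time = (0:299) * bw, trial = rep(1:3, each = 100))
  set.seed(8)
  for (rep in 1:5) {
    evBins <- sort(sample(250, 4))
    ons <- (evBins - 1) * bw
    X <- eventKernelColumns(ons, rep(1, 4), c(0, 0.25), bw, bins)
    for (j in 1:15) {
      d <- j - 1
      hit <- evBins + d
      sameTrial <- hit <= 300 & bins$trial[pmin(hit, 300)] == bins$trial[evBins]
      expected <- sort(hit[sameTrial])
      expect_equal(which(X[, j] != 0), expected)
    }
  }
})

test_that("an event at an exact bin edge lands in the later bin", {
  bw <- 1 / 60
  bins <- data.frame(time = (0:59) * bw, trial = rep(1L, 60))
  X <- eventKernelColumns(2 * bw, 1, c(0, 0.25), bw, bins)
  expect_equal(which(X[, 1] != 0), 3L)
})

test_that("one-hot stimulus columns follow the label-by-sample factorization", {
  s <- fixtureSession()
  oh <- oneHotStimulusColumns(s@trialTable, s@bins, "fixation", 1 / 60)
  expect_equal(length(unique(oh$meta$source)), 16L)   # 4 contrasts x 4 samples
  expect_equal(ncol(oh$X), 16L * 15L)
  # blank (zero-contrast) presentations carry their own indicator
  expect_true(any(grepl("stim_0_s", oh$meta$source)))
  blankCols <- oh$meta$source == "stim_0_s1" & oh$meta$shift == 0
  expect_gt(sum(oh$X[, blankCols]), 0)
  # one-hot: at most one family of a sample position is on per bin
  famOn <- vapply(unique(oh$meta$source)[1:4], function(f)
    oh$X[, oh$meta$source == f & oh$meta$shift == 0], numeric(nrow(s@bins)))
  expect_lte(max(rowSums(famOn)), 1)
})

test_that("drift rows sum to one and the attention-block constraint is enforced", {
  bins <- data.frame(time = seq(0, 99.9, by = 0.1))
  dc <- driftColumns(bins, 10L, 100)
  expect_equal(rowSums(dc$X), rep(1, nrow(bins)))
  expect_error(driftColumns(bins, 1L, 100), "at least 2")
  # blocks of 10 s: a pair lasts 20 s, so at most 6 anchors over 100 s
  expect_error(driftColumns(bins, 10L, 100, blockBounds = seq(0, 90, 10)),
               "configuration error")
  expect_silent(driftColumns(bins, 6L, 100, blockBounds = seq(0, 90, 10)))
})

test_that("analog tent columns: 30 components x 3 anchors give 90 regressors", {
  prof <- matrix(rnorm(30 * 200), 30, 200)
  out <- analogTentColumns(prof, c(-0.1, 0, 0.1), 1 / 60, group = "face")
  expect_equal(ncol(out$X), 90L)
  expect_true(all(out$meta$group == "face"))

  zero <- analogTentColumns(matrix(0, 2, 100), c(-0.1, 0, 0.1), 1 / 60)
  expect_true(all(zero$X == 0))
  expect_error(analogTentColumns(prof, c(0.1, 0), 1 / 60),
               "strictly increasing")
})

test_that("a unit impulse reproduces the sampled tent kernels", {
  bw <- 1 / 60
  imp <- numeric(120); imp[60] <- 1
  out <- analogTentColumns(imp, c(-0.1, 0, 0.1), bw)
  lags <- (-12):12
  W <- tentBasisEval(c(-0.1, 0, 0.1), lags * bw)
  for (a in 1:3) {
    got <- out$X[60 + lags, a]
    expect_equal(got, W[, a], tolerance = 1e-12)
  }
})

test_that("assembled designs partition columns, z-score and reconstruct", {
  f <- fixtureFit()
  d <- f$design
  meta <- columnMeta(d)
  expect_true(all(meta$group %in% c("stimulus", "time", "reward", "drift",
                                    "face", "body")))
  expect_false(any(c("choice", "target", "saccade") %in% meta$group))
  X <- designValues(d)
  act <- !d@zeroVar
  expect_lt(max(abs(colMeans(X[, act]))), 1e-10)
  expect_lt(max(abs(apply(X[, act], 2, var) - 1)), 1e-10)
  raw <- rawDesign(d)
  # drift block in raw units still sums to 1 per row
  expect_equal(rowSums(raw[, meta$group == "drift"]),
               rep(1, nrow(X)), tolerance = 1e-12)
})

test_that("discrimination designs add target, choice and saccade groups", {
  s <- simulateSession(sessionConfig("discrimination", nTrials = 12L,
                                    nUnits = 2L, seed = 5L, blockLength = 4L))
  tr <- sessionTruth(s)
  d <- assembleDesign(s@trialTable, s@bins, tr$profilesFace, tr$profilesBody,
                      variant = "discrimination")
  expect_true(all(c("target", "choice", "saccade") %in% columnGroups(d)))
  expect_equal(sum(columnGroups(d) == "saccade"), 60L)  # 500 ms pre + post
})

test_that("undefined eye samples are excluded when the eye group is active", {
  s <- fixtureSession()
  tr <- sessionTruth(s)
  if (all(s@eye@defined)) skip("no blink in this fixture")
  d0 <- assembleDesign(s@trialTable, s@bins, tr$profilesFace,
                       tr$profilesBody, variant = "fixation")
  dE <- assembleDesign(s@trialTable, s@bins, tr$profilesFace,
                       tr$profilesBody, eyeTrace = s@eye,
                       variant = "fixation")
  expect_true(all(c("eye") %in% columnGroups(dE)))
  expect_equal(sum(columnGroups(dE) == "eye"), 15L)   # 5 signals x 3 anchors
  dropped <- setdiff(binInfo(d0)$binIndex, binInfo(dE)$binIndex)
  expect_true(all(!s@eye@defined[dropped]))
})

test_that("overlapping post-windows are truncated to nonoverlapping bins", {
  short <- simulateSession(sessionConfig(nTrials = 6L, nUnits = 1L,
                                         seed = 2L, itiDuration = 0.5))
  long <- simulateSession(sessionConfig(nTrials = 6L, nUnits = 1L,
                                        seed = 2L, itiDuration = 1.5))
  trS <- short@trialTable@trials
  trL <- long@trialTable@trials
  # with a 0.5-s gap the 1.0-s post window is cut to 0.5 s
  expect_lt(trS$end[1] - trS$start[1], trL$end[1] - trL$start[1])
  expect_equal(trS$end[1], trS$start[2])
  # no bin belongs to two trials
  expect_false(any(duplicated(
    which(short@bins$modeled)[!duplicated(short@bins$trial[short@bins$modeled])])))
})
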