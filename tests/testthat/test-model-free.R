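test_that("movement epochs follow percentile arithmetic and stay disjoint", {
  tr <- seq_len(100) * 1.0
  ep <- detectMovementEpochs(tr, hiPct = 80, loPct = 50)
  expect_length(ep$with, 20L)                       # top 20 of 100
  expect_equal(min(ep$with), 82L)                   # interval t -> bin t + 1
  expect_length(intersect(ep$with, ep$without), 0L)

  ep2 <- detectMovementEpochs(list(tr, rev(tr)), 90, 20)
  expect_length(intersect(ep2$with, ep2$without), 0L)
  expect_error(detectMovementEpochs(tr, 20, 50), "configuration error")
  expect_warning(e0 <- detectMovementEpochs(rep(1, 50), 80, 50), "constant")
  expect_length(e0$with, 0L)
})

test_that("matched pairs respect every stated tolerance and injectivity", {
  s <- fixtureSession()
  mm <- list(computeMotionMatrix(s@face), computeMotionMatrix(s@body))
  ep <- detectMovementEpochs(lapply(mm, averageMotionTrace), 80, 50)
  pairs <- matchEpochConditions(ep, s@trialTable, s@bins, "fixation",
                                s@config@params$binWidth)
  expect_gt(nrow(pairs), 0)
  st <- s@trialTable@stimuli
  expect_true(all(pairs$lagDiff <= 0.010 + 1e-9))
  expect_true(all(pairs$gapDiff <= 0.050 + 1e-9, na.rm = TRUE))
  # matched attributes are identical: contrast, sample, preceding contrast
  expect_true(all(st$label[pairs$withStimRow] == st$label[pairs$woStimRow]))
  expect_true(all(st$sample[pairs$withStimRow] == st$sample[pairs$woStimRow]))
  # one-to-one: no epoch consumed twice, and never paired with itself
  expect_false(any(duplicated(paste(pairs$woStimRow, pairs$woLag))))
  expect_false(any(pairs$withStimRow == pairs$woStimRow))
})

test_that("the modulation index is antisymmetric, bounded and flagged at zero", {
  expect_equal(rateModulationIndex(3, 1), 0.5)
  expect_equal(rateModulationIndex(5, 5), 0)
  expect_equal(rateModulationIndex(2, 0), 1)
  expect_equal(rateModulationIndex(1, 3), -rateModulationIndex(3, 1))
  expect_true(is.na(rateModulationIndex(0, 0)))
  expect_error(rateModulationIndex(-1, 2), "nonnegative")
  set.seed(6)
  ra <- runif(50, 0, 30); rb <- runif(50, 0, 30)
  mi <- rateModulationIndex(ra, rb)
  expect_true(all(mi >= -1 & mi <= 1))
  expect_equal(rateModulationIndex(rb, ra), -mi)
})

test_that("modulation indices are undefined when no pairs exist", {
  s <- fixtureSession()
  out <- modulationIndices(s@spikes, s@trialTable, movenc:::.emptyPairs(),
                           "fixation")
  expect_true(all(is.na(out$MI)))
  expect_equal(out$nPairs, rep(0L, nrow(out)))
  expect_equal(out$windowFrom[1], 0.15)
  expect_equal(out$windowTo[1], 0.45)
})

test_that("drift correction recenters rates without changing their mean", {
  f <- fixtureFit()
  s <- fixtureSession()
  corr <- movenc:::.driftCorrection(f$fit, f$design,
                                    ncol(spikeCounts(s@spikes)))
  expect_equal(dim(corr), c(4L, ncol(spikeCounts(s@spikes))))
  rows <- binInfo(f$design)$binIndex
  expect_equal(rowMeans(corr[, rows]), rep(0, 4), tolerance = 1e-10)
})
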