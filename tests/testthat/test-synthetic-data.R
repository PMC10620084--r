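test_that("trial structure is preserved and events are ordered", {
  tt <- simulateSession(sessionConfig(nTrials = 50L, nUnits = 1L,
                                      seed = 3L))@trialTable
  expect_equal(nrow(tt@trials), 50L)
  expect_true(all(diff(tt@trials$start) > 0))
  byTrial <- split(tt@stimuli$onset, tt@stimuli$trial)
  expect_true(all(vapply(byTrial, function(o) !is.unsorted(o, strictly = TRUE),
                         logical(1))))
  expect_true(all(tt@stimuli$onset >= 0 & tt@stimuli$offset <= tt@sessionEnd))
})

test_that("the same seed reproduces a session bit-identically", {
  cfg <- sessionConfig(nTrials = 8L, nUnits = 2L, seed = 42L,
                       frameHeight = 8L, frameWidth = 8L,
                       couplings = list(face = 0.5))
  a <- simulateSession(cfg)
  b <- simulateSession(cfg)
  expect_identical(spikeCounts(a@spikes), spikeCounts(b@spikes))
  expect_identical(a@face@frames, b@face@frames)
  expect_identical(a@eye@x, b@eye@x)
  expect_identical(sessionTruth(a)$weights, sessionTruth(b)$weights)
})

test_that("zero-coupling session obeys the Poisson law of large numbers", {
  cfg <- sessionConfig(nTrials = 150L, nUnits = 1L, seed = 9L,
                       baselineRate = 10,
                       couplings = list(stimulus = 0, reward = 0, drift = 0))
  s <- simulateSession(cfg)
  expect_true(all(sessionTruth(s)$weights$stimulus == 0))
  expect_true(all(sessionTruth(s)$rates == 10))
  meanRate <- sum(spikeCounts(s@spikes)) /
    (ncol(spikeCounts(s@spikes)) * cfg@params$binWidth)
  expect_lt(abs(meanRate - 10) / 10, 0.05)
})

test_that("simulateSpikes matches the Poisson mean and is deterministic", {
  expect_equal(simulateSpikes(matrix(0, 1, 100), 1 / 60, 1L),
               matrix(0L, 1, 100))
  n <- 1e5L
  cnt <- simulateSpikes(matrix(20, 1, n), 1 / 60, 11L)
  expect_lt(abs(mean(cnt) - 20 / 60) / (20 / 60), 0.02)
  expect_identical(cnt, simulateSpikes(matrix(20, 1, n), 1 / 60, 11L))
  expect_error(simulateSpikes(matrix(-1, 1, 5), 1 / 60), "nonnegative")
})

test_that("motion frames from constant latents carry no motion energy", {
  maps <- list(matrix(1, 6, 6), matrix(2, 6, 6))
  fs <- simulateMotionFrames(matrix(1, 50, 2), maps, noiseSd = 0)
  M <- motionValues(computeMotionMatrix(fs))
  expect_true(all(M == 0))
})

test_that("mismatched spatial maps raise a dimension error", {
  expect_error(simulateMotionFrames(matrix(1, 10, 2),
                                    list(matrix(1, 4, 4), matrix(1, 5, 4))),
               "dimension")
  expect_error(simulateMotionFrames(matrix(1, 10, 2), list(matrix(1, 4, 4))),
               "dimension")
})

test_that("noiseless planted components are recovered exactly; noise adds residual", {
  pl <- plantedFrames(noiseSd = 0)
  mm <- computeMotionMatrix(pl$frames)
  cp <- segmentedSvd(mm, segmentLength = 5, k = 5L)
  M <- motionValues(mm)
  recon <- spatialMaps(cp) %*% temporalProfiles(cp)
  expect_lt(sqrt(sum((M - recon)^2)) / sqrt(sum(M^2)), 1e-6)

  resid <- function(sd) {
    m <- motionValues(computeMotionMatrix(
      plantedFrames(noiseSd = sd)$frames))
    c2 <- segmentedSvd(computeMotionMatrix(plantedFrames(noiseSd = sd)$frames),
                       5, 5L)
    r <- m - spatialMaps(c2) %*% temporalProfiles(c2)
    sum(r^2)
  }
  expect_gt(resid(0.2), resid(0.1))
})

test_that("the retinal confound is zero on controlled bins and identity at gain 0", {
  s <- fixtureSession()
  s0 <- applyRetinalConfound(s, 0)
  expect_identical(spikeCounts(s0@spikes), spikeCounts(s@spikes))
  expect_identical(sessionTruth(s0)$rates, sessionTruth(s)$rates)
  s1 <- applyRetinalConfound(s, 0.05)
  ctrl <- s@bins$fixation
  expect_true(all(sessionTruth(s1)$contrib$retinal[ctrl, ] == 0))
  expect_true(any(sessionTruth(s1)$contrib$retinal[!ctrl, ] != 0))
  expect_error(applyRetinalConfound(s, -1), "configuration error")
})

test_that("invalid configuration fields are reported by name", {
  expect_error(sessionConfig(nTrials = 0), "nTrials")
  expect_error(sessionConfig(binWidth = -1), "binWidth")
  expect_error(sessionConfig(baselineRate = -2), "baselineRate")
  expect_error(sessionConfig(latentAr = 1.2), "latentAr")
})
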