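test_that("ridge at lambda 0 is OLS and shrinkage is monotone", {
  set.seed(2)
  X <- matrix(rnorm(200), 40, 5)
  y <- rnorm(40)
  f0 <- ridgeFit(X, y, 0)
  ols <- lm.fit(cbind(X, 1), y)$coefficients
  expect_equal(as.numeric(f0$weights), unname(ols[1:5]), tolerance = 1e-10)
  expect_equal(f0$intercept, unname(ols[6]), tolerance = 1e-10)

  norms <- vapply(10^(0:9), function(l)
    sqrt(sum(ridgeFit(X, y, l)$weights^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[10], 1e-5)
  expect_error(ridgeFit(X, c(y[-1], NA), 1), "non-finite")
})

test_that("penalty selection returns the sole candidate and is deterministic", {
  set.seed(3)
  X <- matrix(rnorm(600), 120, 5)
  y <- X %*% rnorm(5) + rnorm(120)
  expect_equal(selectPenalty(X, y, grid = 7), 7)
  g <- 10^seq(-2, 4, length.out = 7)
  l1 <- selectPenalty(X, y, g, trial = rep(1:12, each = 10), seed = 5L)
  l2 <- selectPenalty(X, y, g, trial = rep(1:12, each = 10), seed = 5L)
  expect_identical(l1, l2)
  expect_error(selectPenalty(X, y, numeric(0)), "empty")
})

test_that("selected penalty is nondecreasing in observation noise (median over repeats)", {
  set.seed(11)
  X <- matrix(rnorm(150 * 8), 150, 8)
  w <- rnorm(8)
  g <- 10^seq(-2, 6, length.out = 9)
  lams <- replicate(20, {
    eps <- rnorm(150)
    yLow <- X %*% w + 0.5 * eps
    yHigh <- X %*% w + 8 * eps
    tr <- rep(1:15, each = 10)
    sd <- sample.int(1e6, 1)
    c(selectPenalty(X, yLow, g, tr, seed = sd),
      selectPenalty(X, yHigh, g, tr, seed = sd))
  })
  expect_gte(median(lams[2, ]), median(lams[1, ]))
})

test_that("percent VE follows the population-variance convention", {
  expect_equal(percentVE(c(1, 2, 3), c(1, 2, 3)), 100)
  obs <- c(4, 8, 3, 7)
  expect_equal(percentVE(rep(mean(obs), 4), obs), 0)
  expect_equal(percentVE(c(1, 2, 2), c(1, 2, 3)), 100 * (1 - (2 / 9) / (2 / 3)))
  expect_equal(round(percentVE(c(1, 2, 2), c(1, 2, 3)), 1), 66.7)
  expect_warning(v <- percentVE(c(1, 2), c(5, 5)), "undefined")
  expect_true(is.na(v))
  expect_error(percentVE(1:3, 1:2), "aligned")
})

test_that("fold plans partition trials and fold assignment is seeded", {
  p1 <- makeFoldPlan(1:37, 10L, seed = 4L)
  p2 <- makeFoldPlan(1:37, 10L, seed = 4L)
  expect_identical(p1@fold, p2@fold)
  expect_setequal(p1@trial, 1:37)
  expect_true(all(table(p1@fold) %in% 3:4))
})

test_that("every modeled bin is predicted exactly once, by held-out folds only", {
  f <- fixtureFit()
  expect_false(any(is.na(cvPredictions(f$fit))))
  # refitting with the selected penalties reproduces the predictions
  s <- fixtureSession()
  again <- suppressWarnings(crossvalFitPredict(f$design, s@spikes, f$plan,
                                               lambda = f$fit@lambda))
  expect_equal(cvPredictions(again), cvPredictions(f$fit), tolerance = 1e-10)
})

test_that("crossvalidation is honest: misaligned spikes score at or below zero", {
  f <- fixtureFit()
  s <- fixtureSession()
  cnt <- spikeCounts(s@spikes)
  perm <- withr::with_seed(31L, sample.int(ncol(cnt)))
  shuffled <- s@spikes
  SummarizedExperiment::assay(shuffled, "counts") <-
    cnt[, perm, drop = FALSE]
  fitS <- suppressWarnings(crossvalFitPredict(f$design, shuffled, f$plan,
                                              lambda = f$fit@lambda))
  expect_lt(mean(veOverall(fitS)), 0.5)
  expect_gt(mean(veOverall(f$fit)), 5)
})

test_that("percent VE degrades as independent noise is added to the counts", {
  f <- fixtureFit()
  s <- fixtureSession()
  cnt <- spikeCounts(s@spikes)
  ve <- vapply(c(0, 1, 4), function(k) {
    noisy <- s@spikes
    extra <- withr::with_seed(77L + k, matrix(rpois(length(cnt), k * 0.1),
                                              nrow(cnt)))
    SummarizedExperiment::assay(noisy, "counts") <- cnt + extra
    fitN <- suppressWarnings(crossvalFitPredict(f$design, noisy, f$plan,
                                                lambda = f$fit@lambda))
    mean(veOverall(fitN))
  }, numeric(1))
  expect_true(all(diff(ve) < 1))         # nonincreasing within noise
  expect_lt(ve[3], ve[1])
})

test_that("SDF machinery preserves kernel mass and the impulse response", {
  bw <- 1 / 60
  counts <- matrix(0, 3, 120)
  counts[, 50] <- 1
  sdf <- spikeDensityFunction(counts, bw, sd = 0.016)
  expect_equal(sum(sdf) * bw, 1, tolerance = 1e-12)   # one spike per trial
  expect_true(all(sdf[1:49] == 0))                    # causal kernel
  expect_equal(which.max(sdf), 50L)
  k <- movenc:::.halfGaussianKernel(0.016, bw)
  expect_equal(sdf[50:(49 + length(k))], k, tolerance = 1e-12)
})

test_that("split halves of a homogeneous simulation give matching SDFs", {
  bw <- 1 / 60
  set.seed(12)
  counts <- matrix(rpois(400 * 60, 20 * bw), 400, 60)
  a <- spikeDensityFunction(counts[seq(1, 399, 2), ], bw)
  b <- spikeDensityFunction(counts[seq(2, 400, 2), ], bw)
  expect_lt(mean(abs(a - b)) / 20, 0.15)
})

test_that("unit filters apply the rate-per-quartile and epoch-VE criteria", {
  f <- fixtureFit()
  s <- fixtureSession()
  filt <- filterUnits(s@spikes, f$design, f$fit,
                      collapseEpochMask(buildEpochMask(f$design, s@eye,
                                                       fixtureGeometry())))
  expect_true(all(filt$included ==
                    (filt$rateOK & filt$veControlled >= 0 &
                       filt$veUncontrolled >= 0)))
  # synthetic silent-quartile unit is excluded by the rate criterion alone
  cnt <- spikeCounts(s@spikes)
  silent <- cnt
  q4 <- binInfo(s@spikes)$time > 0.75 * max(binInfo(s@spikes)$time)
  silent[1, q4] <- 0L
  sp2 <- s@spikes
  SummarizedExperiment::assay(sp2, "counts") <- silent
  filt2 <- filterUnits(sp2, f$design)
  expect_false(filt2$rateOK[1])
})

test_that("fitted kernels recover the generative ground truth on the fixture", {
  f <- fixtureFit()
  s <- fixtureSession()
  kr <- kernelRecovery(f$fit, f$design, s)
  expect_true(all(kr$stimulus > 0.8))
  expect_true(all(kr$total > 0.8))
})
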