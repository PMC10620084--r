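test_that("epoch masks classify bins exclusively and exhaustively", {
  f <- fixtureFit()
  s <- fixtureSession()
  mask <- buildEpochMask(f$design, s@eye, fixtureGeometry())
  expect_false(anyNA(mask))
  expect_equal(length(mask), nrow(designValues(f$design)))
  bi <- binInfo(f$design)
  # fixation bins with defined eye signal are controlled
  def <- s@eye@defined[bi$binIndex]
  expect_true(all(mask[bi$fixation & def] == "controlled"))
  expect_true(all(mask[!def] == "undefined"))
  # a gaze far off screen can only be uncontrolled_other
  far <- !bi$fixation & def & abs(s@eye@x[bi$binIndex]) > 20
  expect_true(all(mask[far] == "uncontrolled_other"))
  # without eye information every non-fixation bin is uncontrolled_other
  m0 <- buildEpochMask(f$design)
  expect_true(all(m0[!bi$fixation] == "uncontrolled_other"))
})

test_that("group shuffling leaves all other columns bit-identical", {
  f <- fixtureFit()
  red <- movenc:::.shuffleGroups(f$design, "face", seed = 3L)
  grp <- columnGroups(f$design)
  expect_identical(designValues(red)[, grp != "face"],
                   designValues(f$design)[, grp != "face"])
  expect_false(identical(designValues(red)[, grp == "face"],
                         designValues(f$design)[, grp == "face"]))
  # the permutation preserves the z-scoring
  expect_equal(colMeans(designValues(red)[, grp == "face"]),
               colMeans(designValues(f$design)[, grp == "face"]))
  expect_error(movenc:::.shuffleGroups(f$design, "nope", 1L), "naming error")
})

test_that("unique variance is reproducible and isolates the shuffled group", {
  f <- fixtureFit()
  s <- fixtureSession()
  uv1 <- suppressWarnings(
    uniqueVariance(f$design, s@spikes, f$fit, "face", seed = 5L))
  uv2 <- suppressWarnings(
    uniqueVariance(f$design, s@spikes, f$fit, "face", seed = 5L))
  expect_identical(uv1$dve, uv2$dve)
  # the fixture units are face-coupled, so the face group carries signal
  expect_gt(mean(uv1$dve[uv1$epoch == "overall"]), 0.3)
  expect_error(uniqueVariance(f$design, s@spikes, f$fit, "pupilbreath"),
               "naming error")
})

test_that("the task-only model difference equals the joint movement shuffle", {
  f <- fixtureFit()
  s <- fixtureSession()
  red <- suppressWarnings(
    reducedModelVE(f$design, s@spikes, f$fit, c("face", "body"), seed = 9L))
  uv <- suppressWarnings(
    uniqueVariance(f$design, s@spikes, f$fit, c("face", "body"), seed = 9L))
  expect_equal(red$dve, uv$dve)
  expect_equal(red$veFull - red$veTaskOnly, red$dve)
})

test_that("unique variance never exceeds the full model's headroom", {
  f <- fixtureFit()
  s <- fixtureSession()
  uv <- suppressWarnings(
    uniqueVariance(f$design, s@spikes, f$fit, c("face", "body"), seed = 2L))
  ov <- uv[uv$epoch == "overall", ]
  # dVE is bounded by the full model %VE (intercept-only %VE is 0 by the
  # population convention), within shuffle noise
  expect_true(all(ov$dve <= ov$veFull + 0.5))
})

test_that("modulation classification uses a strict threshold and monotone sweeps", {
  uv <- data.frame(unit = sprintf("u%d", 1:4),
                   dve = c(0.15, 0.1, 0.05, 2))
  cl <- classifyModulated(uv, 0.1)
  expect_equal(unname(cl$flags[, 1]), c(TRUE, FALSE, FALSE, TRUE))
  sweep <- classifyModulated(uv, c(0, 0.1, 0.5, 3),
                             area = c("V1", "V1", "V2", "V2"))
  pAll <- sweep$proportions[sweep$proportions$area == "all", ]
  expect_true(all(diff(pAll$proportion) <= 0))
  expect_equal(pAll$proportion, c(1, 2 / 4, 1 / 4, 0))
  v1 <- sweep$proportions[sweep$proportions$area == "V1", ]
  expect_equal(v1$n[1], 2)
})
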