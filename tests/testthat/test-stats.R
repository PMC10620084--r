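test_that("identical paired samples give p = 1 and seeds reproduce", {
  x <- c(1, 2, 3, 4)
  r <- pairedPermutationTest(x, x, nPerm = 200L, seed = 1L)
  expect_equal(r$observed, 0)
  expect_equal(r$pValue, 1)
  set.seed(9)
  a <- rnorm(15); b <- rnorm(15)
  r1 <- pairedPermutationTest(a, b, 500L, seed = 4L)
  r2 <- pairedPermutationTest(a, b, 500L, seed = 4L)
  expect_identical(r1$pValue, r2$pValue)
  expect_gte(r1$pValueAddOne, 1 / 501)
  expect_error(pairedPermutationTest(1:3, 1:4), "input error")
})

test_that("p is invariant to adding a common constant to both pair members", {
  set.seed(10)
  a <- rnorm(12); b <- rnorm(12)
  shift <- rnorm(12)
  r1 <- pairedPermutationTest(a, b, 400L, seed = 2L)
  r2 <- pairedPermutationTest(a + shift, b + shift, 400L, seed = 2L)
  expect_identical(r1$pValue, r2$pValue)
  expect_equal(r1$observed, r2$observed)
})

test_that("distribution comparison returns per-area tests with correction", {
  set.seed(3)
  a <- rnorm(60, 0.1, 0.05)
  b <- rnorm(60, 0, 0.03)
  area <- rep(c("V1", "V2", "V3/V3A"), each = 20)
  out <- compareDistributions(a, b, area)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$tPAdjusted >= out$tP))
  expect_true(all(out$tPAdjusted <= 1))
  expect_true(all(abs(out$cor) <= 1))
})
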