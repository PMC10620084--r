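test_that("motion energy equals the elementwise brute-force differencer", {
  set.seed(1)
  fr <- array(rnorm(10 * 5 * 5), c(10, 5, 5))
  fs <- new("FrameStack", frames = fr, frameRate = 60, view = "face")
  inc <- matrix(FALSE, 5, 5)
  inc[sample(25, 20)] <- TRUE
  mm <- computeMotionMatrix(fs, roiMask(inc))
  expect_equal(dim(motionValues(mm)), c(20L, 9L))
  pix <- which(inc)
  oracle <- matrix(0, 20, 9)
  for (t in 1:9) {
    d <- abs(fr[t + 1, , ] - fr[t, , ])
    oracle[, t] <- d[pix]
  }
  expect_equal(motionValues(mm), oracle)
})

test_that("identical frames give a zero column and sign is removed", {
  fr <- array(0, c(3, 2, 2))
  fr[2, 1, 1] <- 3            # +3 then back down by 3
  fs <- new("FrameStack", frames = fr, frameRate = 60, view = "face")
  M <- motionValues(computeMotionMatrix(fs))
  expect_equal(M[1, ], c(3, 3))
  expect_true(all(M[-1, ] == 0))

  same <- new("FrameStack", frames = array(1, c(2, 2, 2)),
              frameRate = 60, view = "face")
  expect_true(all(motionValues(computeMotionMatrix(same)) == 0))
})

test_that("ROI shape mismatches raise dimension errors", {
  fs <- new("FrameStack", frames = array(0, c(3, 4, 4)),
            frameRate = 60, view = "face")
  expect_error(computeMotionMatrix(fs, roiMask(matrix(TRUE, 3, 3))),
               "dimension")
  expect_error(roiMask(matrix(FALSE, 2, 2)), "at least one")
})

test_that("segmented SVD recovers low-rank structure against a full-SVD oracle", {
  pl <- plantedFrames(nFrames = 400L, k = 3L, noiseSd = 0)
  mm <- computeMotionMatrix(pl$frames)
  M <- motionValues(mm)
  cp <- segmentedSvd(mm, segmentLength = 2, k = 3L)
  sv <- svd(M)
  fullEnergy <- sum(sv$d[1:3]^2)
  recon <- spatialMaps(cp) %*% temporalProfiles(cp)
  expect_gt(sum(recon^2) / fullEnergy, 0.999)
  d <- singularValues(cp)
  expect_true(all(diff(d) <= 0))
})

test_that("one segment spanning the recording matches the global SVD up to sign", {
  pl <- plantedFrames(nFrames = 300L, k = 4L, noiseSd = 0.05)
  mm <- computeMotionMatrix(pl$frames)
  cp <- segmentedSvd(mm, segmentLength = 1e6, k = 4L)
  sv <- svd(motionValues(mm), nu = 4L)
  for (j in 1:4) {
    agree <- abs(sum(spatialMaps(cp)[, j] * sv$u[, j]))
    expect_gt(agree, 1 - 1e-8)
  }
  expect_equal(singularValues(cp), sv$d[1:4], tolerance = 1e-8)
})

test_that("infeasible k is reduced with a warning, never padded; rank 0 errors", {
  pl <- plantedFrames(nFrames = 80L, k = 2L, noiseSd = 0)
  mm <- computeMotionMatrix(pl$frames)
  expect_warning(cp <- segmentedSvd(mm, 2, k = 500L), "feasible rank")
  expect_lte(ncol(spatialMaps(cp)), min(dim(motionValues(mm))))

  still <- new("FrameStack", frames = array(2, c(10, 4, 4)),
               frameRate = 60, view = "face")
  expect_error(segmentedSvd(computeMotionMatrix(still), 1, 2L), "rank 0")
})

test_that("projection recovers profiles exactly for orthonormal spatial maps", {
  pl <- plantedFrames(nFrames = 200L, k = 5L, noiseSd = 0)
  mm <- computeMotionMatrix(pl$frames)
  cp <- segmentedSvd(mm, 2, 5L)
  pr <- projectMotion(mm, cp, 5L)
  # projecting the reconstruction reproduces the profiles (orthonormality)
  expect_equal(crossprod(spatialMaps(cp),
                         spatialMaps(cp) %*% temporalProfiles(cp)),
               pr, tolerance = 1e-10)
  expect_error(projectMotion(mm, cp, 6L), "bounds")
  zero <- mm
  zero@M[] <- 0
  expect_true(all(projectMotion(zero, cp, 3L) == 0))
})

test_that("profile variance is ordered by component for low-rank input", {
  pl <- plantedFrames(nFrames = 500L, k = 4L, noiseSd = 0)
  # make component energies distinct
  lat <- pl$latents %*% diag(c(4, 2, 1, 0.5))
  fs <- simulateMotionFrames(lat, pl$maps[1:4], 0, seed = 2L)
  mm <- computeMotionMatrix(fs)
  cp <- segmentedSvd(mm, 2, 4L)
  v <- apply(temporalProfiles(cp), 1L, var)
  expect_true(all(diff(v) <= 1e-8))
})

test_that("excluding the eye subregion removes its pixels from the decomposition", {
  s <- fixtureSession()
  eye <- sessionTruth(s)$eyeRegion
  expect_true(any(eye))
  full <- roiMask(matrix(TRUE, nrow(eye), ncol(eye)))
  noEye <- excludeSubregion(full, eye, "eye")
  mm <- computeMotionMatrix(s@face, noEye)
  expect_false(any(which(eye) %in% mm@pixelIndex))
  cp <- segmentedSvd(mm, 60, 5L)
  # painted back onto the frame, component energy at eye-only pixels is zero
  img <- matrix(0, nrow(eye), ncol(eye))
  img[mm@pixelIndex] <- rowSums(spatialMaps(cp)^2)
  expect_true(all(img[eye] == 0))
})

test_that("pixel-averaged motion trace equals the brute-force mean", {
  set.seed(4)
  fr <- array(rnorm(8 * 3 * 3), c(8, 3, 3))
  fs <- new("FrameStack", frames = fr, frameRate = 60, view = "body")
  mm <- computeMotionMatrix(fs)
  tr <- averageMotionTrace(mm)
  expect_length(tr, 7L)
  expect_equal(tr, colMeans(motionValues(mm)))
  expect_equal(unname(tr[3]), mean(abs(fr[4, , ] - fr[3, , ])))
})
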